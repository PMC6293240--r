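---
title: "Methods: topic modeling and similarity clustering of forum corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topic modeling and similarity clustering of forum corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery of `forumtopics`, the
assumptions behind it, the defaults and why they were chosen, and the
numerical and design decisions a maintainer should know about.

## The data model

The unit of analysis is the *forum document*: all posts of one forum board,
aggregated into a single text. A corpus is an id-ordered collection of such
documents with thread and post counts. Iteration order is always
lexicographic in `forum_id` — downstream matrices (feature sets, similarity
matrices) need a stable axis, and id order is reproducible across sessions
and locales (a fixed radix collation is used).

Preprocessing is deliberately minimal, matching what general-purpose topic
modeling toolkits do by default: lowercasing, splitting on anything that is
not a letter, digit or intra-word apostrophe, dropping tokens shorter than
two characters and a fixed stopword list. Contractions ("don't", "i'm")
are kept intact — in patient-generated text they are frequent topic
keywords — so the shipped stopword list contains no contractions. There is
no stemming: inflected surface forms ("swollen", "waiting") are
informative in this domain. The stopword list is shipped as a versioned
plain-text file so results are reproducible; callers can substitute their
own.

## Topic model and sampler

Latent Dirichlet allocation with an asymmetric document-topic prior
Dirichlet(α₁…α_K) and a symmetric topic-word prior with concentration β.
Inference is collapsed Gibbs sampling: token *t* of document *d* carrying
word *w* is reassigned to topic *k* with probability proportional to

(n_dk + α_k)(n_wk + β) / (n_·k + Vβ),

counts excluding the token itself. Implementation notes:

* **Sweep order** is document order, then token order; together with a
  single seeded RNG stream this makes runs bit-reproducible for a fixed
  (input, configuration, seed). Initial assignments are uniform random.
* **Count consistency** (column sums of the topic-word matrix equal topic
  totals; row sums of the document-topic matrix equal document lengths) is
  maintained incrementally and verified exhaustively in the tests.
* **Defaults**: α = 50/K symmetric at initialization, β = 0.01, 1000
  sweeps — the conventional defaults for collapsed-Gibbs LDA tools. They
  suit corpora in the range of tens to hundreds of forum documents.
* **Hyperparameter optimization**: every 50 sweeps after a 100-sweep
  burn-in, α is updated by Minka's fixed-point iteration on the
  Dirichlet-multinomial likelihood of the current document-topic counts,
  with components floored at 1e-6 so an unused topic cannot collapse the
  update. The fitted α_k is reported as the topic's *strength*: unlike a
  proportion it can exceed 1, and it measures the topic's overall
  prevalence across all files. (Fixing α instead is supported by setting
  `optimize_alpha_every = 0`.)
* **Degenerate inputs**: a one-word vocabulary, documents emptied by
  filtering, and K equal to the token count are all legal; empty documents
  keep their position and receive the normalized prior as their feature
  row. K larger than the total token count is rejected.

The *file-feature set* is the smoothed mixture matrix with rows
(n_dk + α_k)/(len_d + Σα). Rows sum to 1 by construction — this is asserted
to 1e-9 everywhere it is produced — and entries lie in (0, 1]. Topic
keywords are ranked by the smoothed within-topic probability
(n_wk + β)/(n_·k + Vβ); ties are broken lexicographically so reports are
deterministic. Topic ids are 1-based in every interface.

The collapsed joint log-likelihood log p(w, z | α, β) is tracked per sweep
as a convergence monitor; on synthetic corpora its moving average rises and
flattens within a few hundred sweeps at these problem sizes, which is why
the pipeline default is 500 sweeps and the recovery benchmarks use 300–500.

### Choosing K

The model is fitted at a ladder of K values (default 15, 20, 30), emitting
a full artifact set per K. Deciding at which K the topics stop being "new"
is a judgment about semantics, not statistics, and is left to the analyst;
the package deliberately provides no automatic model-selection criterion
for K.

## Similarity and clustering

Two files are compared by the Euclidean distance between their topic-weight
rows. Distances are mapped to similarities by the affine transform
s = 1 − d/√2, clamped to [0, 1]. The choice is the simplest map that fixes
both endpoints on probability vectors: identical mixtures score exactly 1
and maximally different mixtures (disjoint corners of the simplex, distance
√2) score exactly 0. Because the literature this pipeline follows reports
similarities without defining the transform, the transform is a
configuration option, and a reciprocal alternative 1/(1 + d) is included
for sensitivity analysis.

Topic-topic similarity reuses the same machinery on renormalized column
profiles (each topic's distribution of strength across files); an all-zero
column falls back to a uniform profile rather than dividing by zero.

Clustering at a cutoff (default 0.80) is by connected components of the
thresholded similarity graph — the weakest structural assumption consistent
with reporting groups whose members are chained by pairwise similarity at
or above the cutoff. Components are computed by union-find and emitted in
order of their smallest member label, singletons included, so output is
deterministic. Raising the threshold only refines the partition (a
property-tested invariant). Hierarchical or model-based clustering is out
of scope by design: it would add assumptions the similarity scores do not
support.

## Topic screen by AIC

Per-forum engagement is regressed on topic weights. The outcome is the
pipeline's largest interpretive decision: the default is
log₁₀(post_count + 1) per forum — engagement on a scale where forum sizes
are comparable — and every report records the outcome used; any per-file
response can be injected instead.

Two modes are provided because either is defensible and they answer
slightly different questions:

* `single_topic_screen` (default): one OLS fit per topic,
  y ~ intercept + topic_k, ranked by ascending AIC with ties broken by
  topic id. A perfect fit (RSS = 0, unbounded likelihood) is ranked first
  explicitly rather than given a fake AIC.
* `forward_stepwise`: grows the multi-topic model greedily by best AIC
  improvement until none improves. The last topic column is excluded from
  the candidate pool because feature rows sum to 1, making the full set of
  topic columns perfectly collinear with the intercept.

The AIC convention is fixed and documented:
AIC = n·ln(2π·RSS/n) + n + 2(p + 2), i.e. −2·(maximized Gaussian
log-likelihood) + 2·(parameters, counting slopes, intercept and error
variance). It agrees exactly with `stats::AIC()` on the corresponding `lm`
fit, which the tests use as an independent route. A zero-variance outcome
yields a warning that the ranking is uninformative rather than an error,
so batch pipelines surface the problem without aborting.

## Category statistics

A manual forum-to-category assignment (human qualitative coding, consumed
as a CSV, never invented by the package) is aggregated into per-category
thread and post totals, with unassigned forums reported separately so
totals are conserved. Popularity defaults to post counts with a
thread-count option, since both conventions appear in practice. The
rank-frequency check regresses ln(count) on rank: exactly geometric decay
gives R² = 1 and slope −ln(ratio), and the fit's slope is invariant to
rescaling all counts. Constant counts are degenerate and flagged rather
than fitted.

## The synthetic-data generator

The generator replaces an undeposited real corpus and defines the
conditions under which the pipeline's guarantees are tested. It emulates:

* **Topics**: K_true topic-word distributions drawn from a symmetric
  Dirichlet(β_true = 0.1) over V = 200 words — sparse, realistically
  overlapping word profiles. A `disjoint_topics` switch instead gives each
  topic its own vocabulary block, the well-separated regime used for
  recovery benchmarks.
* **Forum groups**: K_true topics dealt round-robin to n_groups groups;
  group profiles are smoothed simplex corners with leakage
  1/(1 + group_separation); each document's mixture is drawn from a
  Dirichlet with mean exactly its group profile and concentration
  group_separation. One knob therefore controls both profile distinctness
  and within-group tightness; infinity gives disjoint topic support and
  deterministic mixtures, zero removes groups entirely (mixtures from
  Dirichlet(alpha_true)).
* **Engagement signal**: post counts follow
  round(exp(log 500 + Σ effect·weight + N(0, 0.2²))), floored at 1 so the
  log outcome is always defined.

Defaults — 80 forums (a typical site), 4 groups (the familiar four-cluster
structure of related forums), K_true = 5, 200 tokens per document,
group_separation = 20, predictive topics {1, 3} with slopes 2 (ten times
the noise standard deviation) — were chosen once as realistic study
conditions. At separation 20 the expected within-group distance between
mixtures (≈ 0.1) sits well inside the 0.80-similarity cutoff while
between-group distances (≈ 1.3) sit far outside it, so group recovery is a
fair but non-trivial test of the whole chain.

The regression-recovery benchmark uses a deliberately different scenario:
one group, concentration 5, 200 forums. With four tight groups the topic
weights are strongly collinear (a group indicator predicts the outcome
almost as well as its topics), which tests the screen's robustness but not
its calibration; the single-group scenario spreads mixtures across the
simplex (per-topic weight s.d. ≈ 0.16), giving a planted signal roughly
1.6× the outcome noise per topic — strong enough that a correct screen
should find both planted topics nearly always, weak enough that an
incorrect one would not. This was fixed a priori by that power argument.

What the generator does **not** emulate: natural language (no burstiness,
syntax, misspellings or vocabulary growth), user-level posting dynamics,
thread structure, or topic correlations beyond group co-membership.
Passing recovery tests therefore demonstrates that the inference machinery
is correct under its own model assumptions — not that 30 topics, four
clusters or any particular AIC ordering would be recovered from real forum
text.

## Problem sizes and runtime

Test and benchmark sizes were picked so the whole suite runs in well under
a minute of sampling time: normalization checks on a 100-document corpus at
K = 30 for 500 sweeps; topic recovery at K = 2…5 with 200 documents of 200
tokens for 300 sweeps; cluster recovery on the 80-forum default for 400
sweeps; 50 regression replicates on true mixtures. The sampler is compiled
C++ and processes roughly 10⁷–10⁸ token updates per second at these K, so
these sizes are comfortable on a single core, and the same code scales to
corpora orders of magnitude larger.

## Known limitations

* Connected-component clustering is sensitive to single bridging pairs near
  the threshold; the similarity matrices are exported precisely so analysts
  can inspect borderline edges.
* The affine distance-to-similarity map is a convention, not an estimate;
  conclusions that depend on the absolute similarity scale (rather than its
  ordering) should be checked under the reciprocal transform.
* The AIC screen fits one topic at a time by default and inherits the usual
  caveats of marginal screening under collinearity — with tightly grouped
  forums, a topic can rank highly because it proxies a group, not because
  it drives engagement. The stepwise mode mitigates but does not remove
  this.
* `optimize_alpha` maximizes the Dirichlet-multinomial likelihood of the
  *current* counts; on tiny corpora the fixed point can sit at the 1e-6
  floor for rarely used topics. This is intended behavior, not a failure of
  the update.
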