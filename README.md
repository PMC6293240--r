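# forumtopics

Patient-generated text in online health forums — millions of posts spread
over dozens of boards — is too large to read and too unstructured to query.
`forumtopics` organizes such a corpus into a small number of interpretable
topics and groups of similar forums, and screens those topics for
association with forum engagement. It is aimed at health-informatics
researchers who have aggregated forum posts into one document per forum and
want a reproducible, end-to-end analysis rather than a collection of ad-hoc
scripts.

## The model

The core is latent Dirichlet allocation (LDA) fitted by collapsed Gibbs
sampling. Each forum document *d* is a mixture θ<sub>d</sub> over *K*
topics; each topic *k* is a multinomial φ<sub>k</sub> over the vocabulary.
With the multinomials integrated out, every token is resampled from

> P(z = k | rest) ∝ (n<sub>dk</sub> + α<sub>k</sub>) ·
> (n<sub>wk</sub> + β) / (n<sub>·k</sub> + V β)

where n<sub>dk</sub>, n<sub>wk</sub> count current assignments excluding the
token being updated. The asymmetric document-topic concentration α is
re-estimated during sampling by Minka's fixed-point update, and the fitted
α<sub>k</sub> is reported as each topic's *strength* — its overall dominance
across forums (values above 1 are common for dominant topics).

Around the fit:

* **File-feature set** — the D × K matrix with rows
  (n<sub>dk</sub> + α<sub>k</sub>) / (len<sub>d</sub> + Σα); every row sums
  to exactly 1 and no entry can exceed 1.
* **Similarity** — the Euclidean distance between two topic-weight vectors,
  d(x<sub>i</sub>, x<sub>j</sub>) = √Σ<sub>k</sub>(x<sub>ik</sub> −
  x<sub>jk</sub>)², mapped to a score s = 1 − d/√2 ∈ [0, 1] (√2 is the
  largest distance two probability vectors can attain). Files — and topics,
  via renormalized column profiles — are clustered as connected components
  of the graph with edges at similarity ≥ 0.80.
* **Topic screen** — per-topic ordinary least squares of a per-forum
  outcome y (default engagement, log₁₀(post count + 1)) on that topic's
  weight, ranked by Gaussian AIC = n·ln(2π·RSS/n) + n + 2(p + 2); a
  forward-stepwise multi-topic mode is also provided.
* **Synthetic corpora** — a generator that plants known topics, forum
  groups and predictive topics, plus utilities (optimal topic matching,
  adjusted Rand index, hit rates) to score recovery.

## Worked example

```r
library(forumtopics)

g   <- generate_corpus(generator_config(seed = 42))   # 80 forums, 4 groups
bow <- vectorize_corpus(g$corpus)
fit <- fit_lda(bow, K = 5, n_iter = 400, seed = 42)
fit
#> <lda_gibbs> 5 topics, 80 documents, 185 terms, 16075 tokens
#>   sweeps: 400, seed: 42
#>   alpha (topic strengths): 0.911 0.947 0.847 0.801 0.660

feats <- extract_file_feature_set(fit)
all(abs(rowSums(feats$matrix) - 1) < 1e-9)            # rows sum to 1.00
#> TRUE

sim <- file_similarity_matrix(feats)
cl  <- threshold_clusters(sim, 0.80)
lengths(cl$clusters)                                  # planted groups found
#> 20 20 20 20

rk <- rank_topics_by_aic(feats, engagement_outcome(g$corpus))
head(as.data.frame(rk), 3)
#>   topic_id coefficient intercept    aic
#> 1        3      0.7435     2.854 -51.33
#> 2        2     -0.4441     3.146  30.45
#> 3        1     -0.4182     3.133  36.88

recovery_report(g$truth, fit = fit, partition = cl)[c("ari", "mapping")]
#> $ari      1
#> $mapping  5 2 3 1 4
```

The four clusters recover the planted forum groups exactly (adjusted Rand
index 1.0). The AIC screen puts estimated topic 3 first with a positive
coefficient; through the topic matching (`mapping`), estimated topics 3 and
5 are the two planted predictive topics — topic 3's signal is recovered
cleanly, while topic 5 shares a forum group with another topic and its
single-topic fit is correspondingly diluted.

A command-line wrapper with `run`, `generate`, `preprocess`, `fit`,
`similarity`, `regress` and `categories` subcommands is installed at
`system.file("scripts", "forumtopics", package = "forumtopics")`.

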