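# Small corpora keep the Gibbs sampler runs in these tests near-instant;
# recovery-scale runs live in test-acceptance.R.

fit_small <- function(seed = 4, K = 3, n_iter = 60, ...) {
  g <- generate_corpus(generator_config(seed = seed, D = 20, V = 40,
                                        doc_length_mean = 50, K_true = K,
                                        n_groups = min(3L, K),
                                        predictive_topics = 1,
                                        effect_sizes = 2))
  bow <- vectorize_corpus(g$corpus)
  list(bow = bow, fit = fit_lda(bow, K = K, n_iter = n_iter, seed = seed, ...))
}

test_that("sampler keeps counts consistent with assignments", {
  s <- fit_small()
  expect_counts_consistent(s$fit, s$bow)
  # row sums of n_dk are document lengths
  expect_equal(unname(rowSums(s$fit$n_dk)), lengths(s$bow$docs))
})

test_that("sampler is deterministic given the seed and validates input", {
  s1 <- fit_small(seed = 21, n_iter = 30)
  s2 <- fit_small(seed = 21, n_iter = 30)
  expect_identical(s1$fit$assignments, s2$fit$assignments)
  expect_identical(s1$fit$alpha, s2$fit$alpha)

  bow <- s1$bow
  expect_error(fit_lda(bow, K = 1), "at least 2")
  expect_error(fit_lda(bow, K = 1e6), "token count")
  expect_error(fit_lda(bow, K = 3, alpha = c(1, 1)), "length-K")
})

test_that("a one-word vocabulary still yields valid fits", {
  corp <- forum_corpus(make_docs_df(ids = c("F1", "F2"),
                                    texts = c("word word word", "word word"),
                                    posts = c(3L, 2L)))
  bow <- vectorize_corpus(corp, stopwords = character())
  fit <- fit_lda(bow, K = 2, n_iter = 20, seed = 1)
  feats <- extract_file_feature_set(fit)
  expect_true(all(abs(rowSums(feats$matrix) - 1) < 1e-9))
  expect_true(all(is.finite(fit$loglik)))
})

test_that("alpha optimization is directional, symmetric, and matches a numeric optimizer", {
  # all documents on one topic: that component grows, others shrink to floor
  n_dk <- matrix(0L, nrow = 6, ncol = 3)
  n_dk[, 1] <- 50L
  a <- rep(1, 3)
  for (i in 1:20) {
    a_new <- optimize_alpha(n_dk, alpha = a)
    expect_gt(a_new[1], a[1])
    expect_lte(a_new[2], max(a[2], 1e-6))
    a <- a_new
  }
  expect_true(all(a >= 1e-6))

  # symmetric counts give equal components
  sym <- matrix(10L, nrow = 5, ncol = 4)
  a_sym <- optimize_alpha(sym, alpha = rep(2, 4), n_steps = 25)
  expect_lt(diff(range(a_sym)), 1e-9)

  # fixed point maximizes the Dirichlet-multinomial log-likelihood (D=5, K=3)
  # on counts actually drawn from a Dirichlet-multinomial (overdispersed
  # counts are needed for the concentration MLE to be finite)
  set.seed(31)
  theta <- matrix(rgamma(15, 0.5), 5, 3)
  theta <- theta / rowSums(theta)
  n_dk <- t(vapply(1:5, function(d) rmultinom(1, 60, theta[d, ])[, 1],
                   integer(3)))
  storage.mode(n_dk) <- "integer"
  a_fp <- optimize_alpha(n_dk, alpha = rep(1, 3), n_steps = 2000)
  dm_loglik <- function(log_a) {
    a <- exp(log_a)
    len <- rowSums(n_dk)
    sum(lgamma(sum(a)) - lgamma(len + sum(a)) +
          rowSums(lgamma(sweep(n_dk, 2, a, "+"))) - sum(lgamma(a)))
  }
  opt <- optim(log(a_fp), dm_loglik, control = list(fnscale = -1),
               method = "BFGS")
  expect_equal(a_fp, exp(opt$par), tolerance = 1e-4)
  expect_lte(abs(dm_loglik(log(a_fp)) - opt$value), 1e-6)
})

test_that("topic keys rank keywords by smoothed probability with lexicographic ties", {
  s <- fit_small(seed = 8)
  fit <- s$fit
  keys <- extract_topic_keys(fit, top_words = 10)
  expect_equal(keys$topic_id, 1:3)
  expect_equal(keys$strength, fit$alpha)
  terms <- fit$vocabulary$terms
  V <- length(terms)
  for (k in 1:3) {
    prob <- (fit$n_wk[, k] + fit$beta) / (sum(fit$n_wk[, k]) + V * fit$beta)
    ord <- order(-prob, terms, method = "radix")  # full-sort oracle
    expect_equal(strsplit(keys$keywords[k], " ")[[1]], terms[ord[1:10]])
  }
  # top_words beyond V returns all terms
  all_keys <- extract_topic_keys(fit, top_words = V + 50)
  expect_equal(length(strsplit(all_keys$keywords[1], " ")[[1]]), V)

  # hand-built tie: two words with identical counts break lexicographically
  fit2 <- fit
  fit2$n_wk[] <- 0L
  fit2$n_wk[c(2, 1), 1] <- 5L
  k1 <- strsplit(extract_topic_keys(fit2, top_words = 2)$keywords[1], " ")[[1]]
  expect_equal(k1, sort(terms[1:2]))
})

test_that("file-feature rows are smoothed mixtures summing to one", {
  corp <- forum_corpus(make_docs_df(ids = c("F1", "F2", "F3"),
                                    texts = c("aa bb cc dd", "the of", "aa aa"),
                                    posts = c(4L, 0L, 2L)))
  bow <- vectorize_corpus(corp)
  fit <- fit_lda(bow, K = 2, n_iter = 25, seed = 2,
                 optimize_alpha_every = 0)
  feats <- extract_file_feature_set(fit)
  expect_true(all(abs(rowSums(feats$matrix) - 1) < 1e-9))
  expect_true(all(feats$matrix >= 0 & feats$matrix <= 1))
  # the empty document falls back to the normalized prior
  expect_equal(unname(feats$matrix["F2", ]), fit$alpha / sum(fit$alpha))
  # filled documents match the smoothing formula directly
  expect_equal(unname(feats$matrix["F1", ]),
               unname((fit$n_dk["F1", ] + fit$alpha) /
                        (sum(fit$n_dk["F1", ]) + sum(fit$alpha))))
})

test_that("export_top_pairs sorts by strength with topic-id tie-break", {
  feats <- file_features(rbind(c(0.5, 0.3, 0.2), c(0.5, 0.5, 0.0)),
                         doc_ids = c("A", "B"))
  pairs <- export_top_pairs(feats, n_top = 2)
  expect_equal(pairs$A$topic_id, c(1L, 2L))
  expect_equal(pairs$A$strength, c(0.5, 0.3))
  expect_equal(pairs$B$topic_id, c(1L, 2L))  # tie: lower topic id first

  set.seed(77)
  feats <- random_features(6, 5)
  pairs <- export_top_pairs(feats, n_top = 5)
  for (d in 1:6) {
    row <- feats$matrix[d, ]
    ord <- order(-row, seq_along(row))  # brute-force full sort
    expect_equal(pairs[[d]]$topic_id, ord)
    expect_equal(pairs[[d]]$strength, unname(row[ord]))
  }
})

test_that("collapsed log-likelihood matches the closed form and is label-symmetric", {
  # two-token one-word corpus, K = 2, symmetric alpha: closed form by hand.
  # p(w | z) = 1 on a one-word vocabulary, so log p(w, z) = log p(z), the
  # two-draw Dirichlet-multinomial: both tokens on one topic has probability
  # a(1+a) / (2a(1+2a)); a split has a^2 / (2a(1+2a)).
  corp <- forum_corpus(make_docs_df(ids = "F1", texts = "cancer cancer",
                                    posts = 2L))
  bow <- vectorize_corpus(corp, stopwords = character())
  fit <- fit_lda(bow, K = 2, n_iter = 5, seed = 1, optimize_alpha_every = 0)
  a <- fit$alpha[1]
  hand <- if (max(fit$n_dk) == 2) {
    a * (1 + a) / (2 * a * (1 + 2 * a))
  } else {
    a^2 / (2 * a * (1 + 2 * a))
  }
  expect_equal(corpus_log_likelihood(fit), log(hand), tolerance = 1e-12)

  # invariance under topic relabeling with symmetric alpha
  s <- fit_small(seed = 10, n_iter = 20)
  fit <- s$fit
  fit$alpha <- rep(1.5, fit$K)
  ll <- corpus_log_likelihood(fit)
  perm <- c(3L, 1L, 2L)
  fit2 <- fit
  fit2$n_wk <- fit$n_wk[, perm]
  fit2$n_dk <- fit$n_dk[, perm]
  expect_equal(corpus_log_likelihood(fit2), ll, tolerance = 1e-12)
})

test_that("log-likelihood trend is non-decreasing in moving average", {
  g <- generate_corpus(generator_config(seed = 15, D = 40, V = 80,
                                        doc_length_mean = 80))
  bow <- vectorize_corpus(g$corpus)
  fit <- fit_lda(bow, K = 5, n_iter = 250, seed = 15)
  ll <- fit$loglik
  ma <- stats::filter(ll, rep(1 / 50, 50), sides = 1)
  ma <- ma[!is.na(ma)]
  rise <- max(ma) - min(ma)
  expect_gt(utils::tail(ma, 1), ma[1])
  # monotone trend up to small stochastic wiggle relative to the total rise
  expect_true(all(diff(ma) >= -0.02 * rise))
})

test_that("planted two-topic corpora with disjoint vocabularies are recovered", {
  g <- generate_corpus(generator_config(seed = 6, K_true = 2, D = 60, V = 60,
                                        doc_length_mean = 80, n_groups = 1,
                                        group_separation = 2,
                                        disjoint_topics = TRUE,
                                        predictive_topics = 1,
                                        effect_sizes = 2))
  bow <- vectorize_corpus(g$corpus)
  fit <- fit_lda(bow, K = 2, n_iter = 500, seed = 6)
  rep <- recovery_report(g$truth, fit = fit)
  expect_gte(rep$purity, 0.95)
})
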