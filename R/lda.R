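#' Fit latent Dirichlet allocation by collapsed Gibbs sampling
#'
#' Each forum document is modeled as a mixture over `K` latent topics, each
#' topic as a multinomial over the vocabulary. Inference integrates the
#' multinomial parameters out and resamples every token's topic label: the
#' probability of assigning token `t` of document `d` to topic `k` is
#' proportional to `(n_dk + alpha_k) * (n_wk + beta) / (n_.k + V * beta)`,
#' where the counts exclude the token being resampled. Tokens are swept in
#' document order, then token order, so a run is fully determined by the
#' seed.
#'
#' The asymmetric document-topic concentration `alpha` is re-estimated
#' periodically after burn-in by a Minka fixed-point update (see
#' [optimize_alpha()]); the fitted `alpha_k` values are the per-topic
#' strengths reported alongside topic keys, indicating each topic's overall
#' dominance across all forum files. Values above 1 are possible and
#' expected for dominant topics.
#'
#' @param bow a `bow_corpus` from [vectorize_corpus()].
#' @param K number of topics (>= 2, at most the total token count).
#' @param alpha initial concentration: positive scalar (recycled) or
#'   length-`K` vector. Default `50 / K`, symmetric.
#' @param beta symmetric topic-word concentration (> 0), default 0.01.
#' @param n_iter number of full Gibbs sweeps, default 1000.
#' @param optimize_alpha_every re-estimate `alpha` every this many sweeps
#'   after `burnin`; 0 keeps `alpha` fixed. Default 50.
#' @param burnin sweeps before the first alpha update, default 100.
#' @param seed integer RNG seed; the sampler is bit-reproducible given
#'   (input, configuration, seed).
#' @param track_loglik record the collapsed joint log-likelihood after each
#'   sweep (default TRUE).
#' @return An object of class `lda_gibbs` with elements `assignments`
#'   (per-document 1-based topic labels per token), `n_wk` (V x K topic-word
#'   counts), `n_dk` (D x K document-topic counts), `alpha`, `beta`,
#'   `vocabulary`, `doc_ids`, `K`, `loglik` (per-sweep trace) and the
#'   configuration used.
#' @seealso [extract_topic_keys()], [extract_file_feature_set()],
#'   [corpus_log_likelihood()]
#' @examples
#' corp <- generate_corpus(generator_config(seed = 1, D = 20, V = 50,
#'                                          doc_length_mean = 60))$corpus
#' bow <- vectorize_corpus(corp)
#' fit <- fit_lda(bow, K = 5, n_iter = 100, seed = 1)
#' fit
#' @export
fit_lda <- function(bow, K, alpha = NULL, beta = 0.01, n_iter = 1000,
                    optimize_alpha_every = 50, burnin = 100, seed = 1L,
                    track_loglik = TRUE) {
  stopifnot(inherits(bow, "bow_corpus"))
  total_tokens <- sum(lengths(bow$docs))
  if (total_tokens == 0) stop("corpus has no tokens")
  if (K < 2) stop("K must be at least 2")
  if (K > total_tokens) stop("K exceeds the total token count")
  stopifnot(beta > 0, n_iter >= 1)
  if (is.null(alpha)) alpha <- 50 / K
  if (length(alpha) == 1) alpha <- rep(alpha, K)
  if (length(alpha) != K || any(alpha <= 0)) {
    stop("alpha must be a positive scalar or length-K positive vector")
  }
  V <- length(bow$vocabulary$terms)

  set.seed(as.integer(seed))
  res <- .gibbs_lda_cpp(bow$docs, V, as.integer(K), as.numeric(alpha),
                        beta, as.integer(n_iter),
                        as.integer(optimize_alpha_every), as.integer(burnin),
                        isTRUE(track_loglik))
  rownames(res$n_wk) <- bow$vocabulary$terms
  rownames(res$n_dk) <- bow$doc_ids
  structure(list(
    assignments = res$assignments,
    n_wk = res$n_wk,
    n_dk = res$n_dk,
    alpha = as.numeric(res$alpha),
    beta = beta,
    vocabulary = bow$vocabulary,
    doc_ids = bow$doc_ids,
    K = as.integer(K),
    loglik = as.numeric(res$loglik),
    config = list(K = K, alpha_init = alpha, beta = beta, n_iter = n_iter,
                  optimize_alpha_every = optimize_alpha_every,
                  burnin = burnin, seed = seed),
    call = match.call()
  ), class = "lda_gibbs")
}

#' @export
print.lda_gibbs <- function(x, ...) {
  cat(sprintf("<lda_gibbs> %d topics, %d documents, %d terms, %d tokens\n",
              x$K, nrow(x$n_dk), nrow(x$n_wk), sum(x$n_dk)))
  cat(sprintf("  sweeps: %d, seed: %s\n", x$config$n_iter,
              format(x$config$seed)))
  cat("  alpha (topic strengths):",
      paste(sprintf("%.3f", utils::head(x$alpha, 8)), collapse = " "),
      if (x$K > 8) "...\n" else "\n")
  invisible(x)
}

#' @export
summary.lda_gibbs <- function(object, top_words = 8, ...) {
  keys <- extract_topic_keys(object, top_words = top_words)
  cat(sprintf("Latent Dirichlet allocation fit: K = %d\n", object$K))
  cat(sprintf("Final collapsed log-likelihood: %.2f\n",
              corpus_log_likelihood(object)))
  cat("\nTopic keys (strength = fitted alpha_k):\n")
  for (i in seq_len(nrow(keys))) {
    cat(sprintf("  %2d  %8.5f  %s\n", keys$topic_id[i], keys$strength[i],
                keys$keywords[i]))
  }
  invisible(keys)
}

#' @export
logLik.lda_gibbs <- function(object, ...) {
  ll <- corpus_log_likelihood(object)
  structure(ll, df = object$K * (nrow(object$n_wk) - 1) + length(object$alpha),
            class = "logLik")
}

#' Smoothed topic-word probabilities
#'
#' @param object a fitted `lda_gibbs` model.
#' @param ... unused.
#' @return A K x V matrix of within-topic word probabilities
#'   `(n_wk + beta) / (n_.k + V * beta)`; rows sum to 1.
#' @export
coef.lda_gibbs <- function(object, ...) {
  V <- nrow(object$n_wk)
  phi <- t(object$n_wk + object$beta)
  phi <- phi / (colSums(object$n_wk) + V * object$beta)
  rownames(phi) <- paste0("topic", seq_len(object$K))
  phi
}

#' @export
plot.lda_gibbs <- function(x, ...) {
  if (length(x$loglik) == 0) stop("no log-likelihood trace was recorded")
  plot(seq_along(x$loglik), x$loglik, type = "l", xlab = "Gibbs sweep",
       ylab = "collapsed joint log-likelihood",
       main = sprintf("LDA convergence (K = %d)", x$K), ...)
  invisible(x)
}

#' Minka fixed-point update of the document-topic concentration
#'
#' One (or more) fixed-point iterations of the asymmetric Dirichlet
#' concentration under the Dirichlet-multinomial likelihood of the current
#' document-topic counts:
#' `alpha_k <- alpha_k * (sum_d psi(n_dk + alpha_k) - D psi(alpha_k)) /
#'             (sum_d psi(len_d + sum(alpha)) - D psi(sum(alpha)))`.
#' Components are floored at 1e-6 so a topic that is never used cannot drive
#' its concentration to zero. Counts are left untouched.
#'
#' @param state a fitted `lda_gibbs` model, or a bare D x K count matrix.
#' @param alpha starting concentration; defaults to the state's alpha.
#' @param n_steps number of fixed-point iterations (default 1).
#' @return Updated positive concentration vector of length K.
#' @export
optimize_alpha <- function(state, alpha = NULL, n_steps = 1L) {
  if (inherits(state, "lda_gibbs")) {
    n_dk <- state$n_dk
    if (is.null(alpha)) alpha <- state$alpha
  } else {
    n_dk <- state
    if (is.null(alpha)) alpha <- rep(1, ncol(n_dk))
  }
  storage.mode(n_dk) <- "integer"
  stopifnot(length(alpha) == ncol(n_dk), all(alpha > 0))
  for (i in seq_len(n_steps)) alpha <- .minka_step_cpp(as.numeric(alpha), n_dk)
  alpha
}

#' Extract topic keys
#'
#' The topic-keys report: for each topic, its 1-based id, its strength (the
#' fitted Dirichlet concentration `alpha_k`) and its top keywords by smoothed
#' within-topic probability `(n_wk + beta) / (n_.k + V * beta)`. Probability
#' ties are broken lexicographically.
#'
#' @param state a fitted `lda_gibbs` model.
#' @param top_words number of keywords per topic (capped at the vocabulary
#'   size), default 20.
#' @return A data frame of class `topic_keys` with columns `topic_id`,
#'   `strength` and `keywords` (space-joined).
#' @export
extract_topic_keys <- function(state, top_words = 20L) {
  stopifnot(inherits(state, "lda_gibbs"), top_words >= 1)
  terms <- state$vocabulary$terms
  V <- length(terms)
  n <- min(top_words, V)
  keywords <- character(state$K)
  for (k in seq_len(state$K)) {
    prob <- (state$n_wk[, k] + state$beta) /
      (sum(state$n_wk[, k]) + V * state$beta)
    ord <- order(-prob, terms, method = "radix")
    keywords[k] <- paste(terms[ord[seq_len(n)]], collapse = " ")
  }
  structure(data.frame(topic_id = seq_len(state$K), strength = state$alpha,
                       keywords = keywords, stringsAsFactors = FALSE),
            class = c("topic_keys", "data.frame"))
}

#' Extract the file-feature set
#'
#' The document-by-topic matrix of topic strengths per forum file: row `d`
#' is the smoothed mixture `(n_dk + alpha_k) / (len_d + sum(alpha))`. Every
#' row sums to exactly 1, every entry lies in (0, 1], and an empty document
#' falls back to the normalized prior `alpha / sum(alpha)`.
#'
#' @param state a fitted `lda_gibbs` model.
#' @return An object of class `file_features`: list with `matrix` (D x K,
#'   rows named by forum id, columns `topic1..topicK`), `doc_ids` and `K`.
#' @export
extract_file_feature_set <- function(state) {
  stopifnot(inherits(state, "lda_gibbs"))
  m <- sweep(state$n_dk, 2, state$alpha, "+")
  m <- m / (rowSums(state$n_dk) + sum(state$alpha))
  colnames(m) <- paste0("topic", seq_len(state$K))
  file_features(m, doc_ids = state$doc_ids)
}

#' Construct a file-feature set from a matrix
#'
#' @param matrix D x K matrix of nonnegative topic strengths; rows must sum
#'   to 1 within 1e-9.
#' @param doc_ids document labels (defaults to rownames).
#' @return A `file_features` object.
#' @export
file_features <- function(matrix, doc_ids = rownames(matrix)) {
  matrix <- as.matrix(matrix)
  if (is.null(doc_ids)) doc_ids <- paste0("D", seq_len(nrow(matrix)))
  stopifnot(length(doc_ids) == nrow(matrix))
  if (any(matrix < 0) || any(matrix > 1)) {
    stop("feature strengths must lie in [0, 1]")
  }
  if (any(abs(rowSums(matrix) - 1) > 1e-9)) {
    stop("feature rows must sum to 1 within 1e-9")
  }
  rownames(matrix) <- doc_ids
  structure(list(matrix = matrix, doc_ids = as.character(doc_ids),
                 K = ncol(matrix)), class = "file_features")
}

#' @export
print.file_features <- function(x, ...) {
  cat(sprintf("<file_features> %d files x %d topics\n",
              nrow(x$matrix), x$K))
  invisible(x)
}

#' Top topic-strength pairs per file
#'
#' For each file, the `n_top` strongest (topic id, strength) pairs, strength
#' descending with ties broken by ascending topic id — the sparse layout of
#' the per-file feature report.
#'
#' @param features a `file_features` object.
#' @param n_top number of pairs per file (>= 1), capped at K.
#' @return Named list (by file id) of data frames with columns `topic_id`
#'   and `strength`.
#' @export
export_top_pairs <- function(features, n_top = 5L) {
  stopifnot(inherits(features, "file_features"), n_top >= 1)
  n <- min(n_top, features$K)
  out <- lapply(seq_len(nrow(features$matrix)), function(d) {
    row <- features$matrix[d, ]
    ord <- order(-row, seq_along(row))
    data.frame(topic_id = ord[seq_len(n)], strength = unname(row[ord[seq_len(n)]]))
  })
  names(out) <- features$doc_ids
  out
}

#' Collapsed joint log-likelihood of the corpus
#'
#' `log p(w, z | alpha, beta)` with topic-word and document-topic multinomials
#' integrated out: a sum of Dirichlet-multinomial terms over documents and
#' topics. Useful as a convergence monitor across sweeps.
#'
#' @param state a fitted `lda_gibbs` model.
#' @return Finite scalar log-likelihood.
#' @export
corpus_log_likelihood <- function(state) {
  stopifnot(inherits(state, "lda_gibbs"))
  n_dk <- state$n_dk
  n_wk <- state$n_wk
  alpha <- state$alpha
  beta <- state$beta
  V <- nrow(n_wk)
  D <- nrow(n_dk)
  K <- state$K
  a0 <- sum(alpha)
  doc_len <- rowSums(n_dk)
  ll <- D * (lgamma(a0) - sum(lgamma(alpha))) -
    sum(lgamma(doc_len + a0)) +
    sum(lgamma(sweep(n_dk, 2, alpha, "+")))
  topic_tot <- colSums(n_wk)
  ll <- ll + K * (lgamma(V * beta) - V * lgamma(beta)) -
    sum(lgamma(topic_tot + V * beta)) +
    sum(lgamma(n_wk + beta))
  ll
}

#' Write a topic-keys TSV
#'
#' Layout: `topic_id TAB strength TAB space-joined keywords`, one topic per
#' line, no header.
#'
#' @param keys a `topic_keys` data frame from [extract_topic_keys()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topic_keys <- function(keys, path) {
  lines <- sprintf("%d\t%s\t%s", keys$topic_id,
                   format(keys$strength, digits = 6, trim = TRUE),
                   keys$keywords)
  writeLines(lines, path)
  invisible(path)
}

#' Write a file-feature report
#'
#' Two artifacts: a sparse TSV (`doc_id` followed by descending
#' `topic_id TAB strength` pairs, strengths formatted to 3 decimals) and,
#' if `dense_csv` is given, a dense CSV matrix with `doc_id` row labels.
#'
#' @param features a `file_features` object.
#' @param path sparse TSV output path.
#' @param n_top pairs per file in the sparse layout (default all topics).
#' @param dense_csv optional path for the dense matrix CSV.
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(features, path, n_top = features$K,
                              dense_csv = NULL) {
  pairs <- export_top_pairs(features, n_top = n_top)
  lines <- vapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    paste(c(names(pairs)[i],
            rbind(p$topic_id, sprintf("%.3f", p$strength))), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  if (!is.null(dense_csv)) {
    df <- data.frame(doc_id = features$doc_ids, features$matrix,
                     check.names = FALSE)
    utils::write.csv(df, dense_csv, row.names = FALSE)
  }
  invisible(path)
}
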