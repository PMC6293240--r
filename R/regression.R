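#' Ordinary least squares fit
#'
#' Thin wrapper over QR least squares (`lm.fit`) that enforces the
#' preconditions the topic screen relies on: full column rank and more
#' observations than parameters. The design matrix must already contain its
#' intercept column.
#'
#' @param y numeric response vector.
#' @param X design matrix including the intercept column.
#' @return List with `coefficients`, `rss`, `n` and `p` (number of slope
#'   coefficients, i.e. columns minus the intercept).
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, all(is.finite(y)), all(is.finite(X)))
  p <- ncol(X) - 1L
  if (n <= p + 1L) {
    stop("need n > p + 1 observations (n = ", n, ", p = ", p, ")")
  }
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    bad <- colnames(X)[is.na(fit$coefficients)]
    if (length(bad) == 0) bad <- "(unnamed)"
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  list(coefficients = fit$coefficients, rss = sum(fit$residuals^2),
       n = n, p = p)
}

#' Gaussian-likelihood AIC for a least-squares fit
#'
#' The convention is fixed as
#' `AIC = n * log(2 * pi * rss / n) + n + 2 * (p + 2)`, i.e. minus twice the
#' maximized Gaussian log-likelihood plus twice the parameter count, where
#' the parameters are the `p` slopes, the intercept and the error variance.
#' This matches `stats::AIC()` on an `lm` fit of the same model. Lower is
#' better; values are typically negative when residuals are small.
#'
#' @param rss residual sum of squares (> 0; a perfect fit has unbounded
#'   likelihood and is an error the caller must handle).
#' @param n sample size.
#' @param p number of slope coefficients (excluding the intercept).
#' @return Scalar AIC.
#' @export
compute_aic <- function(rss, n, p) {
  stopifnot(n > 0, p >= 0)
  if (rss <= 0) {
    stop("rss must be positive: a perfect fit has unbounded likelihood")
  }
  n * log(2 * pi * rss / n) + n + 2 * (p + 2)
}

#' Default regression outcome: log-scaled forum engagement
#'
#' @param corpus a [forum_corpus()].
#' @return `log10(post_count + 1)` per forum, named by forum id.
#' @export
engagement_outcome <- function(corpus) {
  stopifnot(inherits(corpus, "forum_corpus"))
  stats::setNames(log10(corpus$documents$post_count + 1),
                  corpus$documents$forum_id)
}

#' Rank topics by AIC as predictors of a per-file outcome
#'
#' The regression screen relating topic weight scores to a per-forum
#' response (by default forum engagement, `log10(post_count + 1)`). In
#' `single_topic_screen` mode each topic is fitted alone
#' (`y ~ intercept + topic_k`) and topics are ranked by ascending AIC, ties
#' broken by topic id. In `forward_stepwise` mode the multi-topic model is
#' grown greedily by best AIC improvement until no topic improves the AIC;
#' because feature rows sum to 1 the last topic column is excluded from the
#' stepwise candidate pool (it is perfectly collinear with the intercept and
#' the other topics jointly).
#'
#' @param features a `file_features` object.
#' @param outcome numeric response, one value per file, in file order.
#' @param mode `"single_topic_screen"` (default) or `"forward_stepwise"`.
#' @return For the screen: an object of class `topic_ranking`, a data frame
#'   with `topic_id`, `coefficient`, `intercept` and `aic`, AIC ascending.
#'   For the stepwise mode: a list with `entered` (topic ids in entry
#'   order), `aic_path`, final `coefficients` and `aic`.
#' @export
rank_topics_by_aic <- function(features, outcome,
                               mode = c("single_topic_screen",
                                        "forward_stepwise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(features, "file_features"))
  y <- as.numeric(outcome)
  D <- nrow(features$matrix)
  if (length(y) != D) stop("outcome length must equal the number of files")
  if (!all(is.finite(y))) stop("outcome must be finite")
  if (stats::var(y) == 0) {
    warning("outcome has zero variance; the AIC ranking is uninformative")
  }
  if (mode == "single_topic_screen") {
    res <- lapply(seq_len(features$K), function(k) {
      X <- cbind(intercept = 1, topic = features$matrix[, k])
      f <- fit_ols(y, X)
      # a perfect fit has unbounded likelihood; rank it first explicitly
      aic <- if (f$rss > 0) compute_aic(f$rss, f$n, f$p) else -Inf
      data.frame(topic_id = k, coefficient = unname(f$coefficients[2]),
                 intercept = unname(f$coefficients[1]), aic = aic)
    })
    out <- do.call(rbind, res)
    out <- out[order(out$aic, out$topic_id), , drop = FALSE]
    rownames(out) <- NULL
    structure(out, class = c("topic_ranking", "data.frame"))
  } else {
    candidates <- seq_len(features$K - 1)  # last column dropped: rows sum to 1
    entered <- integer()
    X <- matrix(1, nrow = D, ncol = 1, dimnames = list(NULL, "intercept"))
    rss0 <- sum((y - mean(y))^2)
    if (rss0 <= 0) {
      return(list(entered = integer(), aic_path = numeric(),
                  coefficients = c(intercept = mean(y)), aic = NA_real_))
    }
    best_aic <- compute_aic(rss0, D, 0)
    aic_path <- numeric()
    repeat {
      remaining <- setdiff(candidates, entered)
      if (length(remaining) == 0) break
      trial <- vapply(remaining, function(k) {
        Xk <- cbind(X, features$matrix[, k])
        f <- tryCatch(fit_ols(y, Xk), error = function(e) NULL)
        if (is.null(f) || f$rss <= 0) return(Inf)
        compute_aic(f$rss, f$n, f$p)
      }, numeric(1))
      if (min(trial) >= best_aic) break
      k_best <- remaining[which.min(trial)]
      X <- cbind(X, features$matrix[, k_best])
      colnames(X)[ncol(X)] <- paste0("topic", k_best)
      entered <- c(entered, k_best)
      best_aic <- min(trial)
      aic_path <- c(aic_path, best_aic)
    }
    f <- fit_ols(y, X)
    list(entered = entered, aic_path = aic_path,
         coefficients = f$coefficients, aic = best_aic)
  }
}

#' @export
print.topic_ranking <- function(x, ...) {
  cat(sprintf("<topic_ranking> %d topics, AIC ascending\n", nrow(x)))
  print.data.frame(utils::head(x, 10), digits = 5)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Write a topic ranking as TSV
#'
#' Columns: `topic_id`, optional `topic_label` (joined from a labels table),
#' `coefficient`, `aic`.
#'
#' @param ranking a `topic_ranking`.
#' @param path output path.
#' @param labels optional data frame with columns `topic_id` and `label`.
#' @return `path`, invisibly.
#' @export
write_topic_ranking <- function(ranking, path, labels = NULL) {
  out <- as.data.frame(ranking)
  if (!is.null(labels)) {
    out$topic_label <- labels$label[match(out$topic_id, labels$topic_id)]
    out <- out[, c("topic_id", "topic_label", "coefficient", "aic")]
  } else {
    out <- out[, c("topic_id", "coefficient", "aic")]
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
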