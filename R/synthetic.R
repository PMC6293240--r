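#' Configuration for the synthetic forum-corpus generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' `D` forum documents drawn from a `K_true`-topic mixture model over a
#' `V`-word synthetic vocabulary, `n_groups` planted forum groups with shared
#' topic profiles (the analogue of clusters of related forums), and per-forum
#' post counts depending log-linearly on a chosen subset of topic weights
#' (the planted regression signal).
#'
#' Group profiles are smoothed corners of the topic simplex: the `K_true`
#' topics are dealt round-robin to the groups, and group `g`'s profile puts
#' fraction `1 - leak` uniformly on its own topics and `leak = 1 /
#' (1 + group_separation)` uniformly everywhere. Each document's mixture is
#' drawn from `Dirichlet(group_separation * profile)` — a Dirichlet whose
#' mean is exactly the group profile — so `group_separation` controls both
#' how distinct the group profiles are and how tightly documents hug them.
#' `group_separation = Inf` gives disjoint topic support per group and
#' deterministic mixtures equal to the profile; `group_separation = 0`
#' removes the group structure and draws every mixture from
#' `Dirichlet(alpha_true)`.
#'
#' @param seed integer RNG seed; generation is fully deterministic given the
#'   configuration.
#' @param V vocabulary size (>= 2), default 200.
#' @param K_true true topic count, default 5.
#' @param D number of forum documents, default 80 (a forum site of typical
#'   size).
#' @param doc_length_mean Poisson mean token count per document, default 200.
#' @param alpha_true document-mixture Dirichlet concentration used when
#'   `group_separation = 0` (no planted groups); positive scalar or
#'   length-`K_true` vector, default 0.1.
#' @param beta_true symmetric Dirichlet concentration for topic-word
#'   distributions, default 0.1 (sparse, realistic word profiles).
#' @param n_groups planted forum-group count, default 4.
#' @param group_separation nonnegative scalar (may be `Inf`), default 20.
#' @param predictive_topics topic ids whose weights drive the outcome,
#'   default `c(1, 3)`.
#' @param effect_sizes per-predictive-topic slope on the natural-log scale of
#'   the post count, default `c(2, 2)`.
#' @param noise_sd standard deviation of the Gaussian noise on the log post
#'   count, default 0.2.
#' @param outcome_intercept intercept of the log post-count model, default
#'   `log(500)`.
#' @param disjoint_topics if TRUE, topics get disjoint vocabulary blocks
#'   (each topic's word distribution is supported on its own `V / K_true`
#'   words) — the well-separated regime used for recovery benchmarks.
#'   Default FALSE.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, V = 200L, K_true = 5L, D = 80L,
                             doc_length_mean = 200, alpha_true = 0.1,
                             beta_true = 0.1, n_groups = 4L,
                             group_separation = 20,
                             predictive_topics = c(1L, 3L),
                             effect_sizes = c(2, 2), noise_sd = 0.2,
                             outcome_intercept = log(500),
                             disjoint_topics = FALSE) {
  if (V < 2) stop("V must be at least 2")
  stopifnot(K_true >= 2, D >= 1, doc_length_mean > 0, beta_true > 0,
            n_groups >= 1, n_groups <= K_true, group_separation >= 0,
            noise_sd >= 0)
  if (length(alpha_true) == 1) alpha_true <- rep(alpha_true, K_true)
  stopifnot(length(alpha_true) == K_true, all(alpha_true > 0))
  predictive_topics <- as.integer(predictive_topics)
  if (!all(predictive_topics %in% seq_len(K_true))) {
    stop("predictive_topics must be a subset of 1..K_true")
  }
  stopifnot(length(effect_sizes) == length(predictive_topics))
  if (disjoint_topics && V < K_true) {
    stop("disjoint topics need V >= K_true")
  }
  structure(list(seed = as.integer(seed), V = as.integer(V),
                 K_true = as.integer(K_true), D = as.integer(D),
                 doc_length_mean = doc_length_mean, alpha_true = alpha_true,
                 beta_true = beta_true, n_groups = as.integer(n_groups),
                 group_separation = group_separation,
                 predictive_topics = predictive_topics,
                 effect_sizes = as.numeric(effect_sizes),
                 noise_sd = noise_sd, outcome_intercept = outcome_intercept,
                 disjoint_topics = isTRUE(disjoint_topics)),
            class = "generator_config")
}

.rdirichlet1 <- function(conc) {
  g <- stats::rgamma(length(conc), shape = conc, rate = 1)
  if (sum(g) == 0) {
    # all concentrations effectively zero: fall back to the normalized
    # concentration direction (degenerate but well-defined)
    g <- conc
  }
  g / sum(g)
}

#' Generate a ground-truthed synthetic forum corpus
#'
#' Draws topic-word distributions, planted group profiles, per-document topic
#' mixtures and token streams under the generative model described in
#' [generator_config()], then sets each forum's `post_count` from the planted
#' log-linear outcome model
#' `round(exp(intercept + sum(effect * weight) + N(0, noise_sd)))`, floored
#' at 1. Byte-identical output for a fixed configuration.
#'
#' @param config a [generator_config()].
#' @return A list with `corpus` (a [forum_corpus()]) and `truth`, a list with
#'   `topic_word` (K x V, rows sum to 1), `doc_topic` (D x K, rows sum to 1),
#'   `group_of` (named character vector forum id -> group label),
#'   `outcome_coefficients` (intercept plus per-topic slopes, zeros for
#'   non-predictive topics), and `token_topics` (per-document integer vector
#'   of each token's true topic, aligned with the document's token order).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  K <- config$K_true
  V <- config$V
  D <- config$D
  words <- sprintf("w%05d", seq_len(V))

  # topic-word distributions
  topic_word <- matrix(0, nrow = K, ncol = V,
                       dimnames = list(paste0("topic", seq_len(K)), words))
  if (config$disjoint_topics) {
    block <- rep(seq_len(K), length.out = V)  # round-robin word ownership
    for (k in seq_len(K)) {
      own <- which(block == k)
      topic_word[k, own] <- .rdirichlet1(rep(config$beta_true, length(own)))
    }
  } else {
    for (k in seq_len(K)) {
      topic_word[k, ] <- .rdirichlet1(rep(config$beta_true, V))
    }
  }

  # planted group profiles: smoothed simplex corners
  group_of_topic <- rep(seq_len(config$n_groups), length.out = K)
  leak <- if (is.infinite(config$group_separation)) 0 else
    1 / (1 + config$group_separation)
  profiles <- matrix(0, nrow = config$n_groups, ncol = K)
  for (g in seq_len(config$n_groups)) {
    own <- which(group_of_topic == g)
    profiles[g, own] <- (1 - leak) / length(own)
    profiles[g, ] <- profiles[g, ] + leak / K
  }

  group_of_doc <- rep(seq_len(config$n_groups), length.out = D)
  doc_topic <- matrix(0, nrow = D, ncol = K)
  for (d in seq_len(D)) {
    prof <- profiles[group_of_doc[d], ]
    if (is.infinite(config$group_separation)) {
      doc_topic[d, ] <- prof
    } else if (config$group_separation == 0) {
      doc_topic[d, ] <- .rdirichlet1(config$alpha_true)
    } else {
      doc_topic[d, ] <- .rdirichlet1(config$group_separation * prof)
    }
  }

  # token streams
  token_topics <- vector("list", D)
  texts <- character(D)
  for (d in seq_len(D)) {
    n_tok <- stats::rpois(1, config$doc_length_mean)
    if (n_tok == 0) {
      token_topics[[d]] <- integer()
      texts[d] <- ""
      next
    }
    z <- sample.int(K, n_tok, replace = TRUE, prob = doc_topic[d, ])
    w <- integer(n_tok)
    for (k in unique(z)) {
      idx <- which(z == k)
      w[idx] <- sample.int(V, length(idx), replace = TRUE,
                           prob = topic_word[k, ])
    }
    token_topics[[d]] <- z
    texts[d] <- paste(words[w], collapse = " ")
  }

  # planted outcome: log-linear engagement model
  beta_vec <- numeric(K)
  beta_vec[config$predictive_topics] <- config$effect_sizes
  log_mu <- config$outcome_intercept + doc_topic %*% beta_vec +
    stats::rnorm(D, 0, config$noise_sd)
  post_count <- pmax(1L, as.integer(round(exp(log_mu))))
  # empty forums cannot carry posts under the corpus invariant
  post_count[!nzchar(texts)] <- 0L
  thread_count <- pmax(1L, as.integer(round(post_count / 10)))
  thread_count[post_count == 0L] <- 0L

  ids <- sprintf("F%04d", seq_len(D))
  group_labels <- paste0("G", group_of_doc)
  corp <- forum_corpus(data.frame(
    forum_id = ids,
    forum_name = paste("Forum", seq_len(D)),
    section = group_labels,
    text = texts,
    thread_count = thread_count,
    post_count = post_count,
    stringsAsFactors = FALSE
  ), source_label = sprintf("synthetic(seed=%d)", config$seed))

  rownames(doc_topic) <- ids
  colnames(doc_topic) <- paste0("topic", seq_len(K))
  names(token_topics) <- ids
  truth <- list(
    topic_word = topic_word,
    doc_topic = doc_topic,
    group_of = stats::setNames(group_labels, ids),
    outcome_coefficients = c(intercept = config$outcome_intercept,
                             stats::setNames(beta_vec,
                                             paste0("topic", seq_len(K)))),
    token_topics = token_topics,
    config = config
  )
  list(corpus = corp, truth = truth)
}

#' Write generator ground truth as JSON
#'
#' @param truth the `truth` element of [generate_corpus()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  payload <- list(
    topic_word = truth$topic_word,
    doc_topic = truth$doc_topic,
    group_of = as.list(truth$group_of),
    outcome_coefficients = as.list(truth$outcome_coefficients),
    token_topics = truth$token_topics
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Total variation distance between discrete distributions
#'
#' @param p,q probability vectors of equal length.
#' @return `0.5 * sum(|p - q|)`, in [0, 1].
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  0.5 * sum(abs(p - q))
}

#' Minimum-cost one-to-one assignment (Hungarian algorithm)
#'
#' Solves the linear sum assignment problem on a square cost matrix in
#' O(n^3) using the potentials formulation.
#'
#' @param cost square numeric cost matrix.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 1) return(1L)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j]: row currently assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j]] <- j
  assignment
}

#' Match estimated topics to true topics
#'
#' One-to-one matching of estimated to true topic-word distributions that
#' minimizes the total variation distance, via [solve_assignment()].
#'
#' @param estimated K x V matrix of estimated topic-word distributions.
#' @param truth K x V matrix of true topic-word distributions (same K; when
#'   column names are present on both, columns are aligned by name and
#'   words absent from one side contribute their full mass to the distance).
#' @return List with `mapping` (integer vector: `mapping[k]` is the estimated
#'   topic matched to true topic `k`), `tv` (per-pair TV distances, in true
#'   topic order) and `total_cost`.
#' @export
match_topics <- function(estimated, truth) {
  estimated <- as.matrix(estimated)
  truth <- as.matrix(truth)
  if (nrow(estimated) != nrow(truth)) {
    stop("topic counts differ: ", nrow(estimated), " vs ", nrow(truth))
  }
  if (!is.null(colnames(estimated)) && !is.null(colnames(truth)) &&
      !identical(colnames(estimated), colnames(truth))) {
    all_words <- union(colnames(truth), colnames(estimated))
    pad <- function(m) {
      out <- matrix(0, nrow(m), length(all_words),
                    dimnames = list(rownames(m), all_words))
      out[, colnames(m)] <- m
      out
    }
    estimated <- pad(estimated)
    truth <- pad(truth)
  }
  K <- nrow(truth)
  cost <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      cost[i, j] <- tv_distance(truth[i, ], estimated[j, ])
    }
  }
  mapping <- solve_assignment(cost)
  tv <- cost[cbind(seq_len(K), mapping)]
  list(mapping = mapping, tv = tv, total_cost = sum(tv))
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return Chance-corrected agreement in [-1, 1]; 1 means identical
#'   partitions, 0 is the chance level.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' Evaluate pipeline recovery against generator ground truth
#'
#' Scores how well the fitted pipeline recovered the planted structure:
#' matched topic-word total variation distances (and token-assignment purity)
#' for the topic model, adjusted Rand index of the threshold clustering
#' against the planted forum groups, and the fraction of planted predictive
#' topics found inside the top ranks of the AIC screen.
#'
#' @param truth the `truth` element of [generate_corpus()] output.
#' @param fit optional fitted `lda_gibbs` model on the generated corpus.
#' @param partition optional `cluster_partition` of the file similarity
#'   matrix.
#' @param ranking optional `topic_ranking`. If `fit` is supplied the planted
#'   predictive topic ids are translated through the topic matching before
#'   scoring; if the ranking was computed on the true mixtures, ids are
#'   compared directly.
#' @return List with `tv` (per-topic matched TV distances), `mean_tv`,
#'   `purity`, `mapping`, `ari`, `hit_rate`; components that cannot be
#'   computed from the supplied pieces are `NA`.
#' @export
recovery_report <- function(truth, fit = NULL, partition = NULL,
                            ranking = NULL) {
  out <- list(tv = NA, mean_tv = NA_real_, purity = NA_real_, mapping = NA,
              ari = NA_real_, hit_rate = NA_real_)
  mapping <- NULL
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "lda_gibbs"))
    m <- match_topics(coef(fit), truth$topic_word)
    mapping <- m$mapping
    out$tv <- m$tv
    out$mean_tv <- mean(m$tv)
    out$mapping <- mapping
    # token purity: fitted label (translated) vs planted label, by position
    ids <- fit$doc_ids
    correct <- 0L
    total <- 0L
    for (d in seq_along(ids)) {
      zt <- truth$token_topics[[ids[d]]]
      ze <- fit$assignments[[d]]
      if (length(zt) != length(ze)) {
        stop("token streams are misaligned for document ", ids[d],
             "; was the corpus re-tokenized with a filtering vocabulary?")
      }
      correct <- correct + sum(mapping[zt] == ze)
      total <- total + length(zt)
    }
    out$purity <- if (total > 0) correct / total else NA_real_
  }
  if (!is.null(partition)) {
    memb <- cluster_membership(partition)
    common <- intersect(names(memb), names(truth$group_of))
    out$ari <- adjusted_rand_index(memb[common], truth$group_of[common])
  }
  if (!is.null(ranking)) {
    planted <- truth$config$predictive_topics
    if (!is.null(mapping)) planted <- mapping[planted]
    top <- ranking$topic_id[seq_len(min(length(planted), nrow(ranking)))]
    out$hit_rate <- mean(planted %in% top)
  }
  out
}
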