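# Fixtures and independent oracles shared across the suite. Everything is
# built in code; nothing binary is read from disk.

make_docs_df <- function(ids = c("F100", "F101", "F102"),
                         texts = c("breast biopsy cancer",
                                   "chemo chemo radiation",
                                   "family support friends"),
                         posts = c(10L, 5L, 2L)) {
  texts <- rep_len(texts, length(ids))
  posts <- rep_len(posts, length(ids))
  data.frame(
    forum_id = ids,
    forum_name = paste("Forum", ids),
    section = "",
    text = texts,
    thread_count = pmax(1L, posts %/% 2L),
    post_count = posts,
    stringsAsFactors = FALSE
  )
}

make_tiny_corpus <- function(...) forum_corpus(make_docs_df(...), "fixture")

# random probability-vector rows (Dirichlet(1)) for feature matrices
random_features <- function(D, K) {
  m <- matrix(stats::rgamma(D * K, 1), D, K)
  m <- m / rowSums(m)
  file_features(m, doc_ids = sprintf("F%03d", seq_len(D)))
}

# random valid similarity matrix: similarities of random feature rows
random_similarity <- function(n, K = 4) {
  file_similarity_matrix(random_features(n, K))
}

# brute-force document-frequency counter (vocabulary oracle)
oracle_vocabulary <- function(token_docs, min_df) {
  all_terms <- sort(unique(unlist(token_docs)), method = "radix")
  keep <- vapply(all_terms, function(tm) {
    sum(vapply(token_docs, function(d) tm %in% d, logical(1))) >= min_df
  }, logical(1))
  all_terms[keep]
}

# brute-force pairwise similarity (double-loop oracle)
oracle_similarity <- function(m, transform = "affine") {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        out[i, j] <- 1
      } else {
        d <- sqrt(sum((m[i, ] - m[j, ])^2))
        out[i, j] <- if (transform == "affine") {
          min(1, max(0, 1 - d / sqrt(2)))
        } else 1 / (1 + d)
      }
    }
  }
  out
}

# exhaustive assignment-problem oracle (all permutations)
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

# canonical form of a partition labeling (first-occurrence relabeling), so
# two labelings can be compared for identity of the induced partition
canonical_partition <- function(memb) {
  as.integer(factor(as.character(memb), levels = unique(as.character(memb))))
}

# count consistency between token assignments and the count matrices
expect_counts_consistent <- function(fit, bow = NULL) {
  K <- fit$K
  n_dk <- t(vapply(fit$assignments, function(z) tabulate(z, nbins = K),
                   integer(K)))
  expect_equal(unname(fit$n_dk), unname(n_dk))
  expect_equal(unname(colSums(fit$n_wk)), unname(colSums(n_dk)))
  expect_equal(sum(fit$n_wk), sum(lengths(fit$assignments)))
  if (!is.null(bow)) {
    V <- length(bow$vocabulary$terms)
    n_wk <- matrix(0L, V, K)
    for (d in seq_along(bow$docs)) {
      w <- bow$docs[[d]]
      z <- fit$assignments[[d]]
      for (i in seq_along(w)) n_wk[w[i], z[i]] <- n_wk[w[i], z[i]] + 1L
    }
    expect_equal(unname(fit$n_wk), unname(n_wk))
  }
}
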