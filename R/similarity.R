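#' Euclidean distance between two topic-weight vectors
#'
#' The distance underlying the Euclidean Distance Similarity Measure (EDSM):
#' the square root of the summed squared differences over all K topics.
#'
#' @param x_i,x_j numeric weight vectors of equal length.
#' @return Nonnegative scalar distance.
#' @examples
#' euclidean_distance(c(1, 0, 0), c(0, 1, 0))  # sqrt(2)
#' @export
euclidean_distance <- function(x_i, x_j) {
  if (length(x_i) != length(x_j)) {
    stop("weight vectors differ in length (", length(x_i), " vs ",
         length(x_j), ")")
  }
  if (length(x_i) < 1) stop("weight vectors must have length >= 1")
  if (!all(is.finite(x_i)) || !all(is.finite(x_j))) {
    stop("weight vectors must be finite")
  }
  sqrt(sum((x_i - x_j)^2))
}

#' Map a Euclidean distance to a similarity score
#'
#' The default affine map `1 - d / sqrt(2)`, clamped to [0, 1]. `sqrt(2)` is
#' the largest Euclidean distance attainable between two probability vectors
#' (opposite corners of the simplex), so identical vectors score 1 and
#' maximally different vectors score 0. The reciprocal map `1 / (1 + d)` is
#' available for sensitivity analysis.
#'
#' @param d nonnegative distance (vectorized).
#' @param transform `"affine"` (default) or `"reciprocal"`.
#' @return Similarity score(s) in [0, 1].
#' @export
distance_to_similarity <- function(d, transform = c("affine", "reciprocal")) {
  transform <- match.arg(transform)
  if (any(d < 0)) stop("distance must be nonnegative")
  if (transform == "affine") {
    pmin(1, pmax(0, 1 - d / sqrt(2)))
  } else {
    1 / (1 + d)
  }
}

#' Construct a similarity matrix object
#'
#' @param values symmetric numeric matrix with entries in [0, 1] and unit
#'   diagonal.
#' @param labels axis labels (defaults to rownames).
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- paste0("L", seq_len(nrow(values)))
  stopifnot(nrow(values) == ncol(values), length(labels) == nrow(values))
  if (any(values < 0) || any(values > 1)) stop("similarities must be in [0, 1]")
  if (max(abs(values - t(values))) > 1e-12) stop("matrix must be symmetric")
  if (any(abs(diag(values) - 1) > 0)) stop("diagonal must be exactly 1")
  dimnames(values) <- list(labels, labels)
  structure(list(labels = as.character(labels), values = values),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d\n", nrow(x$values), ncol(x$values)))
  off <- x$values[upper.tri(x$values)]
  if (length(off)) {
    cat(sprintf("  off-diagonal range: [%.3f, %.3f]\n", min(off), max(off)))
  }
  invisible(x)
}

#' @export
plot.similarity_matrix <- function(x, ...) {
  n <- nrow(x$values)
  # darker = more similar, rows top-to-bottom in label order
  graphics::image(seq_len(n), seq_len(n), t(x$values[n:1, , drop = FALSE]),
                  col = grDevices::grey.colors(64, start = 0, end = 1,
                                               rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", zlim = c(0, 1), ...)
  graphics::axis(1, at = seq_len(n), labels = x$labels, las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(n), labels = rev(x$labels), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}

.pairwise_similarity <- function(m, labels, transform) {
  n <- nrow(m)
  vals <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- distance_to_similarity(euclidean_distance(m[i, ], m[j, ]),
                                  transform = transform)
      vals[i, j] <- s
      vals[j, i] <- s
    }
  }
  similarity_matrix(vals, labels = labels)
}

#' File-file similarity matrix
#'
#' Pairwise EDSM similarity between the topic-weight rows of the
#' file-feature set: all file pairs, symmetric, unit diagonal.
#'
#' @param features a `file_features` object with at least 2 files.
#' @param transform passed to [distance_to_similarity()].
#' @return A `similarity_matrix` labeled by file id.
#' @export
file_similarity_matrix <- function(features, transform = "affine") {
  stopifnot(inherits(features, "file_features"))
  if (nrow(features$matrix) < 2) stop("need at least 2 files")
  .pairwise_similarity(features$matrix, features$doc_ids, transform)
}

#' Topic-topic similarity matrix
#'
#' Each topic's profile is its column of strengths across files, renormalized
#' to sum 1 so the same bounded distance-to-similarity map applies; a topic
#' with zero total strength falls back to a uniform profile.
#'
#' @param features a `file_features` object with at least 2 topics.
#' @param transform passed to [distance_to_similarity()].
#' @return A `similarity_matrix` labeled `topic1..topicK`.
#' @export
topic_similarity_matrix <- function(features, transform = "affine") {
  stopifnot(inherits(features, "file_features"))
  if (features$K < 2) stop("need at least 2 topics")
  profiles <- t(features$matrix)
  tot <- rowSums(profiles)
  zero <- tot == 0
  profiles[zero, ] <- 1 / ncol(profiles)
  profiles[!zero, ] <- profiles[!zero, , drop = FALSE] / tot[!zero]
  .pairwise_similarity(profiles, paste0("topic", seq_len(features$K)),
                       transform)
}

#' Report label pairs at or above a similarity cutoff
#'
#' For each label, the associated labels whose similarity score is at least
#' `cutoff` (self excluded), scores rounded to 2 decimals, labels in axis
#' order.
#'
#' @param sim a `similarity_matrix`.
#' @param cutoff similarity threshold in [0, 1] (values above 1 yield empty
#'   associations everywhere).
#' @return Named list (by label) of data frames with columns `label` and
#'   `score`.
#' @export
top_pairs <- function(sim, cutoff = 0.8) {
  stopifnot(inherits(sim, "similarity_matrix"), cutoff >= 0)
  n <- length(sim$labels)
  out <- lapply(seq_len(n), function(i) {
    j <- setdiff(which(sim$values[i, ] >= cutoff), i)
    data.frame(label = sim$labels[j], score = round(sim$values[i, j], 2),
               stringsAsFactors = FALSE)
  })
  names(out) <- sim$labels
  out
}

#' Threshold clustering of a similarity matrix
#'
#' Clusters are the connected components of the graph whose edges join pairs
#' with similarity at or above `threshold` — the weakest structural
#' assumption consistent with reporting groups of items that are pairwise
#' (or chain-wise) similar at a stated cutoff. Singletons are retained, and
#' components are emitted in order of their smallest member label.
#'
#' @param sim a `similarity_matrix`.
#' @param threshold similarity cutoff; 0 yields one cluster, anything above
#'   the largest off-diagonal similarity yields all singletons.
#' @return An object of class `cluster_partition`: list with `threshold` and
#'   `clusters` (list of character label vectors, each sorted).
#' @export
threshold_clusters <- function(sim, threshold = 0.8) {
  stopifnot(inherits(sim, "similarity_matrix"), threshold >= 0)
  n <- length(sim$labels)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (sim$values[i, j] >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(sim$labels, roots)
  comp <- lapply(comp, function(labs) sort(labs, method = "radix"))
  first <- vapply(comp, `[`, character(1), 1)
  comp <- comp[order(first, method = "radix")]
  names(comp) <- NULL
  structure(list(threshold = threshold, clusters = comp),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("<cluster_partition> %d cluster(s) at threshold %.2f\n",
              length(x$clusters), x$threshold))
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  %d: %s\n", i, paste(x$clusters[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Cluster membership as a named vector
#'
#' @param partition a `cluster_partition`.
#' @return Integer cluster index named by label, in label order.
#' @export
cluster_membership <- function(partition) {
  stopifnot(inherits(partition, "cluster_partition"))
  labs <- unlist(partition$clusters, use.names = FALSE)
  idx <- rep(seq_along(partition$clusters), lengths(partition$clusters))
  ord <- order(labs, method = "radix")
  stats::setNames(idx[ord], labs[ord])
}

#' Write a similarity matrix as labeled CSV
#'
#' @param sim a `similarity_matrix`.
#' @param path output path; labels occupy the first row and column.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(sim, path) {
  df <- data.frame(label = sim$labels, sim$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a labeled similarity CSV back
#'
#' @param path CSV written by [write_similarity_csv()].
#' @return A `similarity_matrix`.
#' @export
read_similarity_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(label = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  m <- (m + t(m)) / 2          # absorb decimal round-trip asymmetry
  diag(m) <- 1
  similarity_matrix(m, labels = df$label)
}

#' Write a cluster partition as JSON
#'
#' Layout: `{"threshold": x, "clusters": [[labels...], ...]}`.
#'
#' @param partition a `cluster_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters_json <- function(partition, path) {
  jsonlite::write_json(list(threshold = partition$threshold,
                            clusters = partition$clusters),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
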