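#' Aggregate category popularity over forums
#'
#' The quantitative side of a manual forum categorization: given a
#' forum-to-category assignment, sums thread and post counts per category.
#' Forums not present in the assignment are reported under a separate
#' `unassigned` bucket so totals are conserved.
#'
#' @param assignments data frame with columns `forum_id` and `category`, or a
#'   named character vector (names = forum ids).
#' @param corpus a [forum_corpus()] containing every assigned forum.
#' @param popularity `"posts"` (default) or `"threads"`: which count orders
#'   the report.
#' @return A list with `categories` (data frame `category`, `n_threads`,
#'   `n_posts`, sorted by the chosen popularity descending, ties by category)
#'   and `unassigned` (same columns, one row).
#' @export
aggregate_category_popularity <- function(assignments, corpus,
                                          popularity = c("posts", "threads")) {
  popularity <- match.arg(popularity)
  stopifnot(inherits(corpus, "forum_corpus"))
  if (!is.data.frame(assignments)) {
    assignments <- data.frame(forum_id = names(assignments),
                              category = unname(assignments),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("forum_id", "category") %in% names(assignments)))
  docs <- corpus$documents
  unknown <- setdiff(assignments$forum_id, docs$forum_id)
  if (length(unknown) > 0) {
    stop("assignment references unknown forum(s): ",
         paste(unknown, collapse = ", "))
  }
  cat_of <- assignments$category[match(docs$forum_id, assignments$forum_id)]
  assigned <- !is.na(cat_of)
  agg <- stats::aggregate(
    cbind(n_threads = docs$thread_count[assigned],
          n_posts = docs$post_count[assigned]),
    by = list(category = cat_of[assigned]), FUN = sum
  )
  key <- if (popularity == "posts") agg$n_posts else agg$n_threads
  agg <- agg[order(-key, agg$category), , drop = FALSE]
  rownames(agg) <- NULL
  unassigned <- data.frame(
    category = "(unassigned)",
    n_threads = sum(docs$thread_count[!assigned]),
    n_posts = sum(docs$post_count[!assigned])
  )
  list(categories = agg, unassigned = unassigned)
}

#' Read a forum-to-category assignment CSV
#'
#' @param path CSV with header `forum_id,category`.
#' @return Data frame with character columns `forum_id` and `category`.
#' @export
read_category_assignments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  stopifnot(all(c("forum_id", "category") %in% names(df)))
  df
}

#' Log-linear fit of a rank-frequency distribution
#'
#' Tests whether popularity counts decay log-linearly with rank: counts are
#' sorted descending, assigned ranks 1..n, and `ln(count)` is regressed on
#' rank by ordinary least squares. A clean log-linear (geometric) decay gives
#' R-squared 1 and slope `-ln(ratio)`; constant counts are degenerate and are
#' reported with `r_squared = 0` and `degenerate = TRUE`.
#'
#' @param popularities positive counts (>= 3 of them).
#' @return List with `slope`, `intercept`, `r_squared` and `degenerate`.
#' @export
rank_frequency_loglin_fit <- function(popularities) {
  x <- as.numeric(popularities)
  if (length(x) < 3) stop("need at least 3 counts")
  if (any(x <= 0)) stop("all counts must be positive (log undefined)")
  y <- log(sort(x, decreasing = TRUE))
  rank <- seq_along(y)
  if (stats::var(y) == 0) {
    return(list(slope = 0, intercept = y[1], r_squared = 0,
                degenerate = TRUE))
  }
  fit <- stats::lm(y ~ rank)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - rss / tss,
       degenerate = FALSE)
}
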