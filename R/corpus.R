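#' Construct a forum corpus
#'
#' A forum corpus is the unit of input for the whole pipeline: one document
#' per forum, holding the whitespace-joined text of all posts aggregated from
#' that forum plus its thread and post counts. Documents are always kept in
#' lexicographic `forum_id` order so that every downstream matrix has a
#' stable, reproducible axis.
#'
#' @param documents a data frame with columns `forum_id`, `forum_name`,
#'   `section`, `text`, `thread_count`, `post_count`. `section` may be empty.
#' @param source_label free-text provenance string recorded with the corpus.
#' @return An object of class `forum_corpus`: a list with elements
#'   `documents` (the validated, id-ordered data frame) and `source_label`.
#' @examples
#' docs <- data.frame(
#'   forum_id = c("F2", "F1"), forum_name = c("b", "a"), section = "",
#'   text = c("chemo started", "biopsy results"),
#'   thread_count = c(1L, 1L), post_count = c(2L, 1L)
#' )
#' corp <- forum_corpus(docs, source_label = "example")
#' corp$documents$forum_id  # "F1" "F2"
#' @export
forum_corpus <- function(documents, source_label = "") {
  required <- c("forum_id", "forum_name", "section", "text",
                "thread_count", "post_count")
  missing_cols <- setdiff(required, names(documents))
  if (length(missing_cols) > 0) {
    stop("corpus documents missing required field(s): ",
         paste(missing_cols, collapse = ", "))
  }
  documents <- as.data.frame(documents, stringsAsFactors = FALSE)
  documents$forum_id <- as.character(documents$forum_id)
  documents$forum_name <- as.character(documents$forum_name)
  documents$section <- as.character(documents$section)
  documents$text <- as.character(documents$text)
  documents$thread_count <- .coerce_count(documents$thread_count, "thread_count")
  documents$post_count <- .coerce_count(documents$post_count, "post_count")

  dup <- unique(documents$forum_id[duplicated(documents$forum_id)])
  if (length(dup) > 0) {
    stop("duplicate forum_id in corpus: ", paste(dup, collapse = ", "))
  }
  empty_bad <- !nzchar(documents$text) & documents$post_count > 0
  if (any(empty_bad)) {
    stop("forum(s) with posts but empty text: ",
         paste(documents$forum_id[empty_bad], collapse = ", "))
  }
  # lexicographic id order is the corpus iteration order, using a fixed
  # collation so the axis order does not depend on the session locale
  ord <- order(documents$forum_id, method = "radix")
  documents <- documents[ord, , drop = FALSE]
  rownames(documents) <- NULL
  structure(list(documents = documents,
                 source_label = as.character(source_label)[1]),
            class = "forum_corpus")
}

.coerce_count <- function(x, what) {
  out <- suppressWarnings(as.integer(x))
  if (anyNA(out)) stop(what, " contains non-integer values")
  if (any(out < 0)) stop(what, " must be nonnegative")
  out
}

#' @export
print.forum_corpus <- function(x, ...) {
  cat(sprintf("<forum_corpus> %d forum document(s)", nrow(x$documents)))
  if (nzchar(x$source_label)) cat(" [", x$source_label, "]", sep = "")
  cat("\n")
  cat(sprintf("  total posts: %s, total threads: %s\n",
              format(sum(x$documents$post_count), big.mark = ","),
              format(sum(x$documents$thread_count), big.mark = ",")))
  invisible(x)
}

#' @export
length.forum_corpus <- function(x) nrow(x$documents)

#' Read a forum corpus from JSON
#'
#' The on-disk schema is a top-level object
#' `{"source_label": string, "documents": [...]}` where each document record
#' has the fields `forum_id`, `forum_name`, `section`, `text`,
#' `thread_count`, `post_count`. Records are re-ordered by `forum_id` on
#' read; duplicate ids and missing fields are validation errors.
#'
#' @param path path to a corpus JSON file.
#' @return A [forum_corpus()] object.
#' @seealso [write_corpus_json()]
#' @export
read_corpus_json <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  if (!is.list(raw) || is.null(raw$documents)) {
    stop("corpus JSON must be an object with a 'documents' array: ", path)
  }
  docs <- raw$documents
  if (length(docs) == 0 || (is.data.frame(docs) && nrow(docs) == 0)) {
    docs <- data.frame(forum_id = character(), forum_name = character(),
                       section = character(), text = character(),
                       thread_count = integer(), post_count = integer(),
                       stringsAsFactors = FALSE)
  }
  forum_corpus(docs, source_label = if (is.null(raw$source_label)) "" else
    raw$source_label)
}

#' Write a forum corpus to JSON
#'
#' Inverse of [read_corpus_json()]: `read_corpus_json(write_corpus_json(c, p))`
#' reproduces `c` field for field, including non-ASCII code points.
#'
#' @param corpus a [forum_corpus()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_json <- function(corpus, path) {
  stopifnot(inherits(corpus, "forum_corpus"))
  payload <- list(source_label = corpus$source_label,
                  documents = corpus$documents)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a site summary table
#'
#' A site summary table lists, per forum website, the number of forums,
#' threads, posts and (optionally) members. The CSV header is
#' `site_name,forums,threads,posts,members`, with `NA` marking a missing
#' member count (never 0).
#'
#' @param path CSV file path.
#' @return A data frame with one row per site; `members` is `NA` where the
#'   site does not publish a member count.
#' @export
read_site_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(site_name = "character"))
  required <- c("site_name", "forums", "threads", "posts", "members")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("site table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("forums", "threads", "posts")) {
    tab[[col]] <- .coerce_count(tab[[col]], col)
  }
  tab$members <- suppressWarnings(as.integer(tab$members))
  if (any(tab$members < 0, na.rm = TRUE)) stop("members must be nonnegative")
  tab
}

#' Summarize a site table
#'
#' Computes exact integer totals over sites and each site's share of the
#' total post volume as a percentage rounded to one decimal.
#'
#' @param rows a data frame as returned by [read_site_table()] (columns
#'   `site_name`, `forums`, `threads`, `posts`, `members`).
#' @return A list with `total_forums`, `total_threads`, `total_posts`,
#'   `total_members` (over sites reporting one), and `shares`, a data frame
#'   of `site_name` and `post_share_pct`.
#' @export
summarize_site_table <- function(rows) {
  if (nrow(rows) < 1) stop("site table must have at least one row")
  total_posts <- sum(as.numeric(rows$posts))
  if (total_posts == 0) {
    stop("total post count is zero; post shares are undefined")
  }
  shares <- data.frame(
    site_name = rows$site_name,
    post_share_pct = round(100 * as.numeric(rows$posts) / total_posts, 1),
    stringsAsFactors = FALSE
  )
  list(
    total_forums = sum(rows$forums),
    total_threads = sum(as.numeric(rows$threads)),
    total_posts = total_posts,
    total_members = sum(as.numeric(rows$members), na.rm = TRUE),
    shares = shares
  )
}
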