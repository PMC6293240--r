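#' Default English stopword list
#'
#' A fixed, versioned list of English function words shipped with the
#' package. The list deliberately contains no contractions: topic keywords
#' in patient forum text frequently include surface forms such as "don't"
#' and "i'm", which carry discourse signal and must survive filtering.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "forumtopics")
  readLines(path, encoding = "UTF-8")
}

#' Tokenize free text
#'
#' Lowercases, normalizes curly apostrophes to ASCII, splits on any character
#' that is not a letter, digit or intra-word apostrophe, strips leading and
#' trailing apostrophes, then drops stopwords and tokens shorter than two
#' characters. Tokenization is idempotent on its own space-joined output.
#'
#' @param text a character scalar (empty text yields an empty token vector).
#' @param stopwords character vector of lowercase stopwords to remove.
#' @return Character vector of tokens in original order, with multiplicity.
#' @examples
#' tokenize("Breast biopsy, CANCER!", stopwords = character())
#' tokenize("I don't know", stopwords = c("i", "know"))
#' @export
tokenize <- function(text, stopwords = default_stopwords()) {
  if (length(text) != 1) stop("tokenize expects a single string")
  if (is.na(text) || !nzchar(text)) return(character())
  text <- tolower(text)
  text <- gsub("’", "'", text, fixed = TRUE)
  toks <- strsplit(text, "[^\\p{L}\\p{N}']+", perl = TRUE)[[1]]
  toks <- gsub("^'+|'+$", "", toks)
  toks <- toks[nchar(toks) >= 2]
  toks[!(toks %in% stopwords)]
}

#' Build a vocabulary from tokenized documents
#'
#' Keeps the tokens appearing in at least `min_df` distinct documents and
#' assigns contiguous integer ids in lexicographic term order, so the
#' vocabulary is deterministic for a given input.
#'
#' @param token_docs list of per-document token vectors.
#' @param min_df minimum document frequency (>= 1) for a term to be kept.
#' @return An object of class `vocabulary`: list with `terms` (ordered
#'   character vector) and `index` (named integer vector mapping term to
#'   1-based id).
#' @export
build_vocabulary <- function(token_docs, min_df = 1L) {
  stopifnot(min_df >= 1)
  df_counts <- table(unlist(lapply(token_docs, unique), use.names = FALSE))
  terms <- names(df_counts)[df_counts >= min_df]
  terms <- sort(terms, method = "radix")
  if (length(terms) == 0) {
    stop("vocabulary is empty after document-frequency filtering; ",
         "lower min_df (currently ", min_df, ")")
  }
  index <- stats::setNames(seq_along(terms), terms)
  structure(list(terms = terms, index = index), class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d terms\n", length(x$terms)))
  invisible(x)
}

#' Vectorize a forum corpus into bag-of-words form
#'
#' Tokenizes every forum document, builds the vocabulary, and encodes each
#' document as a sequence of token ids with multiplicity (the collapsed Gibbs
#' sampler operates on token instances, not on a binary matrix). Tokens
#' outside the vocabulary are dropped; otherwise token counts are conserved.
#' Documents that become empty are retained at their position with length 0.
#'
#' @param corpus a [forum_corpus()].
#' @param stopwords stopword vector passed to [tokenize()].
#' @param min_df minimum document frequency passed to [build_vocabulary()].
#' @return An object of class `bow_corpus`: list with `vocabulary`, `docs`
#'   (list of integer id vectors, 1-based) and `doc_ids` (aligned forum ids).
#' @export
vectorize_corpus <- function(corpus, stopwords = default_stopwords(),
                             min_df = 1L) {
  stopifnot(inherits(corpus, "forum_corpus"))
  if (nrow(corpus$documents) == 0) stop("corpus is empty")
  token_docs <- lapply(corpus$documents$text, tokenize, stopwords = stopwords)
  if (all(lengths(token_docs) == 0)) {
    stop("all documents are empty after tokenization and stopword removal")
  }
  vocab <- build_vocabulary(token_docs, min_df = min_df)
  docs <- lapply(token_docs, function(toks) {
    ids <- unname(vocab$index[toks])
    as.integer(ids[!is.na(ids)])
  })
  structure(list(vocabulary = vocab, docs = docs,
                 doc_ids = corpus$documents$forum_id),
            class = "bow_corpus")
}

#' @export
print.bow_corpus <- function(x, ...) {
  cat(sprintf("<bow_corpus> %d documents, %d terms, %d tokens\n",
              length(x$docs), length(x$vocabulary$terms),
              sum(lengths(x$docs))))
  invisible(x)
}
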