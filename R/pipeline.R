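#' Read a flat key = value pipeline configuration file
#'
#' Minimal TOML-like dialect: one `key = value` pair per line, `#` comments,
#' blank lines ignored, values unquoted or double-quoted; comma-separated
#' values become vectors. Keys mirror the arguments of [run_pipeline()].
#'
#' @param path configuration file path.
#' @return Named list of character (or character vector) values.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (expected key = value): ", ln)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    if (grepl(",", val, fixed = TRUE)) {
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    }
    out[[key]] <- val
  }
  out
}

.stage_seed <- function(seed, stage_index) {
  # documented fan-out: one global seed, per-stage offsets, so any stage can
  # be re-run standalone with the seed it saw inside the full pipeline
  as.integer(seed) + as.integer(stage_index)
}

#' Run the full forum-topics pipeline
#'
#' Orchestrates the end-to-end workflow on a corpus JSON: tokenization and
#' vectorization, one LDA fit per entry of the `K` ladder, and per fit the
#' topic-keys TSV, feature-set TSV and dense CSV, file and topic similarity
#' CSVs, top-pairs report, threshold-cluster JSON and AIC ranking TSV, plus
#' an optional category popularity report and a run manifest recording the
#' configuration, per-stage seeds and the MD5 content hash of every artifact.
#' Rerunning with an identical configuration and seed reproduces identical
#' hashes.
#'
#' @param corpus_path path to a corpus JSON ([read_corpus_json()] schema).
#' @param out_dir output directory (created if needed).
#' @param k_ladder integer vector of topic counts to fit, default
#'   `c(15, 20, 30)`.
#' @param seed global seed; per-stage seeds are derived as `seed + stage
#'   index`.
#' @param n_iter Gibbs sweeps per fit, default 500.
#' @param stopwords_path optional stopword file (one token per line);
#'   defaults to the shipped list.
#' @param min_df minimum document frequency for the vocabulary, default 1.
#' @param similarity_threshold cluster cutoff, default 0.80.
#' @param similarity_transform passed to the similarity constructors.
#' @param regression_mode `"single_topic_screen"` or `"forward_stepwise"`.
#' @param outcome_name label recorded for the outcome; the outcome itself is
#'   forum engagement, `log10(post_count + 1)`.
#' @param assignments_path optional forum-to-category CSV for the category
#'   popularity report.
#' @param labels_path optional topic labels CSV (`topic_id,label`) joined
#'   into ranking reports.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json` in `out_dir`).
#' @export
run_pipeline <- function(corpus_path, out_dir, k_ladder = c(15L, 20L, 30L),
                         seed = 1L, n_iter = 500L, stopwords_path = NULL,
                         min_df = 1L, similarity_threshold = 0.80,
                         similarity_transform = "affine",
                         regression_mode = "single_topic_screen",
                         outcome_name = "log10(post_count + 1)",
                         assignments_path = NULL, labels_path = NULL) {
  if (!file.exists(corpus_path)) {
    stop("startup validation: corpus path does not exist: ", corpus_path)
  }
  if (!is.null(stopwords_path) && !file.exists(stopwords_path)) {
    stop("startup validation: stopword path does not exist: ", stopwords_path)
  }
  if (!is.null(assignments_path) && !file.exists(assignments_path)) {
    stop("startup validation: assignment path does not exist: ",
         assignments_path)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  warnings_log <- character()
  artifacts <- character()
  timings <- list()
  emit <- function(path) {
    artifacts <<- c(artifacts, path)
    path
  }
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      unlink(artifacts)  # no partial output set on failure
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  corpus <- run_stage("read_corpus", read_corpus_json(corpus_path))
  stopwords <- if (is.null(stopwords_path)) default_stopwords() else
    readLines(stopwords_path, encoding = "UTF-8")
  bow <- run_stage("vectorize",
                   vectorize_corpus(corpus, stopwords = stopwords,
                                    min_df = min_df))
  outcome <- engagement_outcome(corpus)

  for (ki in seq_along(k_ladder)) {
    K <- as.integer(k_ladder[ki])
    tag <- sprintf("k%02d", K)
    fit <- run_stage(paste0("fit_", tag),
                     fit_lda(bow, K = K, n_iter = n_iter,
                             seed = .stage_seed(seed, ki)))
    keys <- extract_topic_keys(fit)
    feats <- extract_file_feature_set(fit)
    write_topic_keys(keys, emit(file.path(out_dir,
                                          paste0("topic_keys_", tag, ".tsv"))))
    write_feature_set(feats,
                      emit(file.path(out_dir,
                                     paste0("feature_set_", tag, ".tsv"))),
                      n_top = min(5L, K),
                      dense_csv = emit(file.path(out_dir,
                                                 paste0("feature_set_", tag,
                                                        ".csv"))))
    fsim <- run_stage(paste0("similarity_", tag), {
      f <- file_similarity_matrix(feats, transform = similarity_transform)
      write_similarity_csv(f, emit(file.path(out_dir,
                                             paste0("file_similarity_", tag,
                                                    ".csv"))))
      tsim <- topic_similarity_matrix(feats, transform = similarity_transform)
      write_similarity_csv(tsim,
                           emit(file.path(out_dir,
                                          paste0("topic_similarity_", tag,
                                                 ".csv"))))
      f
    })
    pairs <- top_pairs(fsim, cutoff = similarity_threshold)
    pair_lines <- vapply(names(pairs), function(id) {
      p <- pairs[[id]]
      paste0(id, "\t", paste(sprintf("%s (%.2f)", p$label, p$score),
                             collapse = ", "))
    }, character(1))
    writeLines(pair_lines,
               emit(file.path(out_dir, paste0("top_pairs_", tag, ".tsv"))))
    clusters <- threshold_clusters(fsim, threshold = similarity_threshold)
    write_clusters_json(clusters,
                        emit(file.path(out_dir,
                                       paste0("clusters_", tag, ".json"))))
    ranking <- run_stage(paste0("regress_", tag), {
      withCallingHandlers(
        rank_topics_by_aic(feats, outcome, mode = regression_mode),
        warning = function(w) {
          warnings_log <<- c(warnings_log,
                             paste0("regress_", tag, ": ",
                                    conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
    })
    if (regression_mode == "single_topic_screen") {
      labels <- if (!is.null(labels_path)) {
        utils::read.csv(labels_path, stringsAsFactors = FALSE)
      } else NULL
      write_topic_ranking(ranking,
                          emit(file.path(out_dir,
                                         paste0("topic_ranking_", tag,
                                                ".tsv"))),
                          labels = labels)
    } else {
      jsonlite::write_json(ranking,
                           emit(file.path(out_dir,
                                          paste0("stepwise_", tag, ".json"))),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if (!is.null(assignments_path)) {
    assign_df <- read_category_assignments(assignments_path)
    pop <- run_stage("categories",
                     aggregate_category_popularity(assign_df, corpus))
    utils::write.csv(rbind(pop$categories, pop$unassigned),
                     emit(file.path(out_dir, "category_popularity.csv")),
                     row.names = FALSE)
  }

  hashes <- as.list(tools::md5sum(sort(artifacts)))
  names(hashes) <- basename(sort(artifacts))
  manifest <- list(
    corpus_path = corpus_path,
    source_label = corpus$source_label,
    n_documents = nrow(corpus$documents),
    k_ladder = as.integer(k_ladder),
    seed = as.integer(seed),
    stage_seeds = stats::setNames(
      vapply(seq_along(k_ladder), function(i) .stage_seed(seed, i),
             integer(1)),
      sprintf("fit_k%02d", as.integer(k_ladder))),
    n_iter = as.integer(n_iter),
    min_df = as.integer(min_df),
    similarity_threshold = similarity_threshold,
    similarity_transform = similarity_transform,
    aic_convention = "n*log(2*pi*rss/n) + n + 2*(p + 2)",
    regression_mode = regression_mode,
    outcome = outcome_name,
    warnings = warnings_log,
    stage_seconds = timings,
    artifact_md5 = hashes
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
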