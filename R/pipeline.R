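# End-to-end pipeline driver: configuration, per-book scoring with partial
# failure handling, and Table-shaped TSV/JSON reporting.

#' Pipeline configuration
#'
#' All paths must exist when the pipeline starts (checked up front, each
#' miss a configuration error). The config round-trips losslessly through
#' its JSON representation ([read_pipeline_config()]).
#'
#' @param vectors Path to the `.vec` embedding file.
#' @param labels Path to the label config (JSON/YAML).
#' @param corpus Path to the corpus manifest TSV.
#' @param out Output directory (created if needed).
#' @param tagger_lexicon Path to the tagger lexicon TSV.
#' @param pnr_mode `"sum"` or `"mean"` (see [aggregate_book()]).
#' @param window Optional odd smoothing window for arcs.
#' @param bins Histogram bin count.
#' @param seed Integer seed recorded in the run metadata (the analysis
#'   itself is deterministic; the seed feeds anything downstream that
#'   samples).
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(vectors, labels, corpus, out,
                            tagger_lexicon,
                            pnr_mode = c("sum", "mean"),
                            window = NULL, bins = 40L, seed = 1L,
                            log_level = c("info", "quiet")) {
  cfg <- structure(
    list(
      vectors = vectors, labels = labels, corpus = corpus, out = out,
      tagger_lexicon = tagger_lexicon,
      pnr_mode = match.arg(pnr_mode),
      window = if (is.null(window)) NULL else as.integer(window),
      bins = as.integer(bins),
      seed = as.integer(seed),
      log_level = match.arg(log_level)
    ),
    class = "pipeline_config"
  )
  for (key in c("vectors", "labels", "corpus", "tagger_lexicon")) {
    if (!file.exists(cfg[[key]])) {
      abort_sb(sprintf("config path '%s' does not exist: %s", key, cfg[[key]]),
               "sentibook_config_error")
    }
  }
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose keys match the [pipeline_config()]
#'   arguments; relative paths are resolved against the file's directory.
#' @param ... Overrides applied on top of the file (flags win).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  overrides <- list(...)
  for (nm in names(overrides)) raw[[nm]] <- overrides[[nm]]
  base <- dirname(path)
  for (key in c("vectors", "labels", "corpus", "tagger_lexicon", "out")) {
    if (!is.null(raw[[key]]) && !file.exists(raw[[key]]) &&
        !grepl("^/", raw[[key]])) {
      raw[[key]] <- file.path(base, raw[[key]])
    }
  }
  do.call(pipeline_config, raw)
}

pipe_log <- function(cfg, fmt, ...) {
  if (cfg$log_level != "quiet") message(sprintf(fmt, ...))
}

write_tsv <- function(df, path) {
  write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
}

#' Run the full scoring pipeline
#'
#' Loads vectors, labels (validated before any scoring starts) and the
#' corpus, scores every book, and writes `sentences.tsv` (per-sentence
#' affect), `books.tsv` (one row per book with the 18 profile features and
#' dispersions), `corpus.tsv` (per-feature mean/sd/sem across books) and
#' `run.json` (coverage, failures, config echo) into the output directory.
#' A book that cannot be scored (e.g. entirely out-of-vocabulary) is
#' recorded as a failure while the remaining books complete; the failure
#' count is in the returned summary and in `run.json`.
#'
#' @param config A [pipeline_config()] or a path to a JSON config.
#' @return Invisibly, a list: `books` (profile tibble), `corpus`
#'   (corpus_profile or NULL when fewer than two books scored),
#'   `sentences`, `hit_rate`, `failures` (named character vector of error
#'   messages), `paths`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  table <- read_word_vectors(cfg$vectors)
  labels <- read_label_config(cfg$labels)
  check <- validate_labels(labels, table)
  if (!check$ok) {
    abort_sb(
      sprintf("label validation failed; unresolvable: %s",
              paste(check$missing, collapse = ", ")),
      "sentibook_label_error"
    )
  }
  tagger <- lexicon_tagger(read_tagger_lexicon(cfg$tagger_lexicon))
  books <- read_corpus(cfg$corpus, tagger)
  if (length(books) == 0L) {
    abort_sb("corpus is empty", "sentibook_empty_error")
  }
  pipe_log(cfg, "scoring %d book(s)", length(books))
  sentences_all <- list()
  profiles <- list()
  failures <- character()
  for (book in books) {
    res <- tryCatch({
      sa <- score_book(book, labels, table)
      stats <- compute_corpus_stats(book)
      prof <- aggregate_book(sa, stats, book_id = book$book_id,
                             pnr_mode = cfg$pnr_mode)
      cov <- if (prof$n_content > 0L) prof$n_scored / prof$n_content else NA
      pipe_log(cfg, "  %s: %d sentences, coverage %.1f%%",
               book$book_id, nrow(sa), 100 * cov)
      sa$book_id <- book$book_id
      list(sentences = sa[, c("book_id", setdiff(names(sa), "book_id"))],
           profile = prof)
    }, sentibook_error = function(e) e)
    if (inherits(res, "error")) {
      failures[[book$book_id]] <- conditionMessage(res)
      pipe_log(cfg, "  %s: FAILED (%s)", book$book_id, conditionMessage(res))
    } else {
      sentences_all[[book$book_id]] <- res$sentences
      profiles[[book$book_id]] <- res$profile
    }
  }
  if (length(profiles) == 0L) {
    abort_sb("every book failed to score", "sentibook_scoring_error")
  }
  sentences <- do.call(rbind, unname(sentences_all))
  book_table <- do.call(rbind, unname(profiles))
  corpus <- if (nrow(book_table) >= 2L) aggregate_corpus(book_table) else NULL
  scored_books <- books[vapply(books, function(b) b$book_id, character(1)) %in%
                          book_table$book_id]
  hit_rate <- compute_hit_rate(scored_books, table)
  paths <- list(
    sentences = file.path(cfg$out, "sentences.tsv"),
    books = file.path(cfg$out, "books.tsv"),
    corpus = file.path(cfg$out, "corpus.tsv"),
    run = file.path(cfg$out, "run.json")
  )
  write_tsv(sentences, paths$sentences)
  write_tsv(book_table, paths$books)
  if (!is.null(corpus)) write_tsv(corpus$features, paths$corpus)
  jsonlite::write_json(
    list(
      n_books = length(books),
      n_scored = nrow(book_table),
      n_failed = length(failures),
      failures = as.list(failures),
      hit_rate = hit_rate,
      n_books_negative_aap =
        if (is.null(corpus)) sum(book_table$aap < 0) else
          corpus$n_books_negative_aap,
      pnr_mode = cfg$pnr_mode,
      seed = cfg$seed
    ),
    paths$run, auto_unbox = TRUE, pretty = TRUE
  )
  pipe_log(cfg, "done: %d scored, %d failed, hit-rate %.1f%%",
           nrow(book_table), length(failures), 100 * hit_rate)
  invisible(list(
    books = book_table, corpus = corpus, sentences = sentences,
    hit_rate = hit_rate, failures = failures, paths = paths
  ))
}
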