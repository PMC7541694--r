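# Emotional narrative arcs: per-sentence affect time series, moving-average
# smoothing, AAP histograms, and most-extreme word extraction.

#' Centered moving-average smoothing
#'
#' Window must be odd and positive; at the edges the window truncates to
#' the available neighbors, so output length always equals input length.
#' Window 1 is the identity.
#'
#' @param series Numeric series.
#' @param window Odd positive integer, at most `length(series)`.
#' @return Smoothed numeric series of the same length.
#' @examples
#' smooth_series(c(0, 1, 2, 3, 4), 3)  # 0.5 1 2 3 3.5
#' @export
smooth_series <- function(series, window) {
  if (!is_count(window) || window %% 2L == 0L) {
    abort_sb("`window` must be an odd positive integer",
             "sentibook_config_error")
  }
  n <- length(series)
  if (window > n) {
    abort_sb("`window` must not exceed the series length",
             "sentibook_config_error")
  }
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(series[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

default_window <- function(n) {
  w <- max(3L, round(0.1 * n))
  if (w %% 2L == 0L) w <- w + 1L
  min(w, if (n %% 2L == 1L) n else n - 1L)
}

#' Build an emotional narrative arc
#'
#' Extracts one affect feature (by default the sentence AAP) as a series
#' over sentence position, linearly interpolates undefined sentences
#' (gaps at the series edges take the nearest defined value), and smooths
#' with a centered moving average. The fraction of the smoothed curve lying
#' strictly above zero summarizes the overall positivity of the arc.
#'
#' @param sentences Sentence-affect tibble from [score_book()].
#' @param feature Column to trace (default `"aap"`); any affect column
#'   works, e.g. `"happiness"`.
#' @param window Odd smoothing window; default
#'   `max(3, round(0.1 * n_sentences))` made odd.
#' @return An object of class `emotional_arc`: `feature`, `raw` (with NA
#'   gaps), `smoothed`, `window`, `area_above_zero_fraction`.
#' @export
build_arc <- function(sentences, feature = "aap", window = NULL) {
  if (!is.data.frame(sentences) || nrow(sentences) == 0L) {
    abort_sb("`sentences` must be a non-empty sentence-affect table",
             "sentibook_config_error")
  }
  if (!feature %in% names(sentences)) {
    abort_sb(sprintf("unknown arc feature '%s'", feature),
             "sentibook_config_error")
  }
  ord <- order(sentences$sentence_index)
  raw <- sentences[[feature]][ord]
  n <- length(raw)
  defined <- which(!is.na(raw))
  if (length(defined) == 0L) {
    abort_sb("arc undefined: feature is NA for every sentence",
             "sentibook_scoring_error")
  }
  filled <- if (length(defined) == n) {
    raw
  } else if (length(defined) == 1L) {
    rep(raw[defined], n)
  } else {
    approx(defined, raw[defined], xout = seq_len(n), rule = 2)$y
  }
  if (is.null(window)) window <- default_window(n)
  smoothed <- smooth_series(filled, window)
  structure(
    list(
      feature = feature,
      raw = raw,
      smoothed = smoothed,
      window = as.integer(window),
      area_above_zero_fraction = mean(smoothed > 0)
    ),
    class = "emotional_arc"
  )
}

#' @export
print.emotional_arc <- function(x, ...) {
  cat(sprintf(
    "<emotional_arc> %s over %d sentences (window %d); %.1f%% above zero\n",
    x$feature, length(x$raw), x$window, 100 * x$area_above_zero_fraction))
  invisible(x)
}

#' Histogram of sentence AAP values
#'
#' Bins are half-open `[a, b)` with the last bin closed; by default 40
#' equal-width bins spanning the observed range. Counts sum to the number
#' of sentences with a defined AAP; the mean AAP is reported alongside,
#' which is the quantity a positivity (Pollyanna) bias shifts above zero.
#'
#' @param sentences Sentence-affect tibble from [score_book()].
#' @param bins Either a single count of equal-width bins (default 40) or a
#'   numeric vector of bin edges.
#' @return A list: `edges`, `counts`, `mean`, `n`.
#' @export
aap_histogram <- function(sentences, bins = 40) {
  x <- sentences$aap
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    abort_sb("histogram undefined: no sentence has a defined AAP",
             "sentibook_scoring_error")
  }
  if (length(bins) == 1L) {
    if (!is_count(bins)) {
      abort_sb("`bins` must be a positive bin count or an edge vector",
               "sentibook_config_error")
    }
    rng <- range(x)
    if (rng[[1L]] == rng[[2L]]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[[1L]], rng[[2L]], length.out = bins + 1L)
  } else {
    edges <- sort(as.numeric(bins))
    if (min(x) < edges[[1L]] || max(x) > edges[[length(edges)]]) {
      abort_sb("bin edges do not span the observed AAP range",
               "sentibook_config_error")
    }
  }
  h <- graphics::hist(x, breaks = edges, right = FALSE,
                      include.lowest = TRUE, plot = FALSE)
  list(edges = edges, counts = h$counts, mean = mean(x), n = length(x))
}

#' Most positive and most negative word types of a book
#'
#' Returns the `k` highest-AAP and `k` lowest-AAP distinct content-word
#' types occurring in the book (wordcloud data), each with its occurrence
#' count. Lists are ordered by extremity (positive: descending AAP;
#' negative: ascending); ties are broken alphabetically. If fewer than `k`
#' scored types occur, all are returned with a notice.
#'
#' @param book A [book_document()].
#' @param scores Named numeric vector mapping word types (case-folded) to
#'   AAP, e.g. from [score_word_types()].
#' @param k Number of types per polarity.
#' @return A list with tibbles `positive` and `negative`, columns `word`,
#'   `aap`, `frequency`.
#' @export
top_affective_words <- function(book, scores, k) {
  stopifnot(inherits(book, "book_document"))
  if (!is_count(k)) {
    abort_sb("`k` must be a positive integer", "sentibook_config_error")
  }
  if (length(scores) == 0L || is.null(names(scores))) {
    abort_sb("`scores` must be a non-empty named numeric vector",
             "sentibook_config_error")
  }
  types <- tolower(unlist(lapply(book$sentences, function(s) {
    filter_content_words(s$tokens)$surface
  })))
  if (length(types) == 0L) {
    abort_sb("book has no content words", "sentibook_empty_error")
  }
  freq <- table(types)
  present <- intersect(names(freq), names(scores))
  if (length(present) < k) {
    message(sprintf(
      "only %d scored content-word types available (k = %d); returning all",
      length(present), k))
  }
  aap <- scores[present]
  take <- function(decreasing) {
    ord <- order(if (decreasing) -aap else aap, present)
    sel <- present[head(ord, min(k, length(present)))]
    tibble::tibble(word = sel, aap = unname(aap[sel]),
                   frequency = as.integer(freq[sel]))
  }
  list(positive = take(TRUE), negative = take(FALSE))
}

#' AAP of every content-word type in a book
#'
#' Convenience companion to [top_affective_words()]: scores each distinct
#' case-folded content-word type of the book.
#'
#' @param book A [book_document()].
#' @param labels A [label_config()].
#' @param table A [word_vector_table()].
#' @return Named numeric vector of AAP values (NA-free: unresolvable types
#'   are dropped).
#' @export
score_word_types <- function(book, labels, table) {
  stopifnot(inherits(book, "book_document"))
  lm <- label_matrices(labels, table)
  ct <- do.call(rbind, lapply(book$sentences, function(s) {
    filter_content_words(s$tokens)
  }))
  if (is.null(ct) || nrow(ct) == 0L) {
    abort_sb("book has no content words", "sentibook_empty_error")
  }
  key <- tolower(ct$surface)
  first <- !duplicated(key)
  words <- key[first]
  lemmas <- ct$lemma[first]
  vals <- vapply(seq_along(words), function(i) {
    v <- vector_lookup(words[[i]], table, fallback_form = lemmas[[i]])
    if (is.null(v)) return(NA_real_)
    u <- v / sqrt(sum(v * v))
    mean(lm$positive %*% u) - mean(lm$negative %*% u)
  }, numeric(1))
  names(vals) <- words
  vals[!is.na(vals)]
}
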