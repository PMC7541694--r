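# Affect scoring: word AAP and discrete-emotion scores, sentence aggregation
# with POS-conditional means and positive/negative counts, and book/corpus
# profiles.

resolve_token <- function(token, table) {
  if (is.character(token)) {
    vector_lookup(token, table)
  } else if (is.list(token) || is.data.frame(token)) {
    vector_lookup(token$surface[[1L]], table,
                  fallback_form = token$lemma[[1L]])
  } else {
    abort_sb("`token` must be a word string or a tagged token",
             "sentibook_config_error")
  }
}

#' Affective-aesthetic potential of a single word
#'
#' AAP is the mean cosine similarity between the word's vector and every
#' positive label, minus the mean cosine similarity with every negative
#' label; it therefore lies in `[-2, 2]`. A word whose vector cannot be
#' resolved is not scorable and yields `NA` (a value, not an error).
#'
#' @param token A word string, or a tagged-token row with `surface` and
#'   `lemma` (the lemma is used as lookup fallback).
#' @param labels A [label_config()] validated against `table`.
#' @param table A [word_vector_table()].
#' @return AAP in `[-2, 2]`, or `NA` if the word has no vector.
#' @export
word_aap <- function(token, labels, table) {
  lm <- label_matrices(labels, table)
  v <- resolve_token(token, table)
  if (is.null(v)) return(NA_real_)
  u <- v / sqrt(sum(v * v))
  mean(lm$positive %*% u) - mean(lm$negative %*% u)
}

#' Discrete-emotion score of a single word
#'
#' The cosine similarity between the word's vector and the single emotion
#' label's vector, in `[-1, 1]`.
#'
#' @inheritParams word_aap
#' @param emotion_label The emotion's label word (must resolve in `table`).
#' @return Cosine in `[-1, 1]`, or `NA` if the word has no vector.
#' @export
word_emotion <- function(token, emotion_label, table) {
  lv <- vector_lookup(emotion_label, table)
  if (is.null(lv)) {
    abort_sb(sprintf("emotion label '%s' not in vector table", emotion_label),
             "sentibook_label_error")
  }
  v <- resolve_token(token, table)
  if (is.null(v)) return(NA_real_)
  cosine_similarity(v, lv)
}

# Per-content-word scores for one sentence; NULL when nothing is scorable.
sentence_word_scores <- function(tokens, lm, table) {
  ct <- filter_content_words(tokens)
  if (nrow(ct) == 0L) return(NULL)
  vecs <- lapply(seq_len(nrow(ct)), function(i) {
    vector_lookup(ct$surface[[i]], table, fallback_form = ct$lemma[[i]])
  })
  found <- !vapply(vecs, is.null, logical(1))
  if (!any(found)) {
    return(list(n_content = nrow(ct), n_scored = 0L))
  }
  u <- matrix(unlist(vecs[found]), ncol = table$dimension, byrow = TRUE)
  u <- u / sqrt(rowSums(u * u))
  aap <- rowMeans(u %*% t(lm$positive)) - rowMeans(u %*% t(lm$negative))
  emo <- u %*% t(lm$emotion)  # n_scored x 6
  colnames(emo) <- EMOTION_NAMES
  list(
    n_content = nrow(ct),
    n_scored = sum(found),
    pos_class = ct$pos_class[found],
    surface = ct$surface[found],
    aap = aap,
    emotions = emo
  )
}

sentence_affect_row <- function(index, ws) {
  pos_mean <- function(cls) {
    if (is.null(ws) || ws$n_scored == 0L) return(NA_real_)
    sel <- ws$pos_class == cls
    if (!any(sel)) NA_real_ else mean(ws$aap[sel])
  }
  scored <- !is.null(ws) && ws$n_scored > 0L
  row <- tibble::tibble(
    sentence_index = index,
    n_content = if (is.null(ws)) 0L else ws$n_content,
    n_scored = if (is.null(ws)) 0L else ws$n_scored,
    aap = if (scored) mean(ws$aap) else NA_real_,
    aap_noun = pos_mean("NOUN"),
    aap_verb = pos_mean("VERB"),
    aap_adjective = pos_mean("ADJ"),
    aap_adverb = pos_mean("ADV"),
    n_positive = if (scored) sum(ws$aap > 0) else 0L,
    n_negative = if (scored) sum(ws$aap < 0) else 0L
  )
  for (e in EMOTION_NAMES) {
    row[[e]] <- if (scored) mean(ws$emotions[, e]) else NA_real_
  }
  # stable column order: counts last
  row[, c("sentence_index", "n_content", "n_scored", "aap",
          "aap_noun", "aap_verb", "aap_adjective", "aap_adverb",
          EMOTION_NAMES, "n_positive", "n_negative")]
}

#' Score one sentence
#'
#' Computes the sentence's mean AAP over scorable content words, the
#' POS-conditional AAP means (NA for empty POS subsets), the six
#' discrete-emotion means, and the counts of positive (AAP > 0) and
#' negative (AAP < 0) words. Words with AAP exactly 0 count as neither.
#' Out-of-vocabulary words are excluded from every mean but tracked via
#' `n_content` vs `n_scored`.
#'
#' @param sentence A sentence record (list with `index` and `tokens`) from a
#'   [book_document()], or a tagged-token tibble (index then taken as 0).
#' @param labels A [label_config()].
#' @param table A [word_vector_table()].
#' @return A one-row tibble (`sentence_index`, `n_content`, `n_scored`,
#'   `aap`, `aap_noun`, `aap_verb`, `aap_adjective`, `aap_adverb`, the six
#'   emotions, `n_positive`, `n_negative`). All means are NA iff
#'   `n_scored` is 0.
#' @export
score_sentence <- function(sentence, labels, table) {
  lm <- label_matrices(labels, table)
  if (is.data.frame(sentence)) {
    sentence <- list(index = 0L, tokens = sentence)
  }
  ws <- sentence_word_scores(sentence$tokens, lm, table)
  sentence_affect_row(sentence$index, ws)
}

#' Score every sentence of a book
#'
#' @param book A [book_document()].
#' @inheritParams score_sentence
#' @return A tibble with one [score_sentence()] row per sentence, in order.
#' @export
score_book <- function(book, labels, table) {
  stopifnot(inherits(book, "book_document"))
  lm <- label_matrices(labels, table)
  rows <- lapply(book$sentences, function(s) {
    sentence_affect_row(s$index, sentence_word_scores(s$tokens, lm, table))
  })
  do.call(rbind, rows)
}

mean_sd_sem <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(c(NA_real_, NA_real_, NA_real_))
  s <- if (n > 1L) sd(x) else NA_real_
  c(mean(x), s, if (n > 1L) s / sqrt(n) else NA_real_)
}

#' Aggregate sentence scores into a book profile
#'
#' Each affect feature is the unweighted mean over the sentences where it is
#' defined, reported with its sd and sem across sentences. The book PNR is,
#' by default, the ratio of summed positive to summed negative word counts
#' over all sentences (`pnr_mode = "sum"`, robust to sentences without
#' negative words); `pnr_mode = "mean"` instead averages per-sentence
#' ratios over sentences with at least one negative word. A book without a
#' single negative word gets an infinite PNR, flagged with a warning rather
#' than dropped.
#'
#' @param sentences Tibble from [score_book()].
#' @param stats One-row tibble from [compute_corpus_stats()].
#' @param book_id Identifier carried into the profile.
#' @param pnr_mode `"sum"` (default) or `"mean"`; see Details.
#' @return A one-row tibble: `book_id`, the 18 profile features
#'   (`n_sentences`, `words_per_sentence`, `tokens`, `types`, `word_length`,
#'   `ttr`, `aap`, `aap_noun`, `aap_verb`, `aap_adjective`, `aap_adverb`,
#'   the six emotions, `pnr`) plus `<feature>_sd` / `<feature>_sem`
#'   companions for the sentence-aggregated affect features and coverage
#'   bookkeeping (`n_content`, `n_scored`).
#' @export
aggregate_book <- function(sentences, stats, book_id = "book",
                           pnr_mode = c("sum", "mean")) {
  pnr_mode <- match.arg(pnr_mode)
  if (!is.data.frame(sentences) || nrow(sentences) == 0L) {
    abort_sb("`sentences` must be a non-empty sentence-affect table",
             "sentibook_config_error")
  }
  if (all(is.na(sentences$aap))) {
    abort_sb(sprintf("book '%s': no sentence has any scorable content word",
                     book_id),
             "sentibook_scoring_error")
  }
  profile <- tibble::tibble(
    book_id = book_id,
    n_sentences = stats$n_sentences,
    words_per_sentence = stats$mean_words_per_sentence,
    tokens = stats$n_tokens,
    types = stats$n_types,
    word_length = stats$mean_word_length,
    ttr = stats$type_token_ratio
  )
  for (f in c("aap", "aap_noun", "aap_verb", "aap_adjective", "aap_adverb",
              EMOTION_NAMES)) {
    mss <- mean_sd_sem(sentences[[f]])
    profile[[f]] <- mss[[1L]]
    profile[[paste0(f, "_sd")]] <- mss[[2L]]
    profile[[paste0(f, "_sem")]] <- mss[[3L]]
  }
  if (pnr_mode == "sum") {
    npos <- sum(sentences$n_positive)
    nneg <- sum(sentences$n_negative)
    if (nneg == 0L) {
      warning(sprintf("book '%s': no negative words; PNR is infinite",
                      book_id), call. = FALSE)
      profile$pnr <- Inf
    } else {
      profile$pnr <- npos / nneg
    }
    profile$pnr_sd <- NA_real_
    profile$pnr_sem <- NA_real_
  } else {
    ratios <- sentences$n_positive / sentences$n_negative
    ratios <- ratios[is.finite(ratios)]
    if (length(ratios) == 0L) {
      warning(sprintf("book '%s': no sentence with negative words; PNR is infinite",
                      book_id), call. = FALSE)
      profile$pnr <- Inf
      profile$pnr_sd <- NA_real_
      profile$pnr_sem <- NA_real_
    } else {
      mss <- mean_sd_sem(ratios)
      profile$pnr <- mss[[1L]]
      profile$pnr_sd <- mss[[2L]]
      profile$pnr_sem <- mss[[3L]]
    }
  }
  profile$n_content <- sum(sentences$n_content)
  profile$n_scored <- sum(sentences$n_scored)
  cols <- c("book_id", PROFILE_FEATURES,
            paste0(rep(AFFECT_FEATURES, each = 2L), c("_sd", "_sem")),
            "n_content", "n_scored")
  profile[, cols]
}

#' Aggregate book profiles into a corpus summary
#'
#' Reports, for every profile feature, the mean, sd and sem across books,
#' plus the count of books whose overall AAP is negative (a direct read-out
#' of a positivity bias: under the Pollyanna hypothesis that count is
#' small).
#'
#' @param profiles Tibble of [aggregate_book()] rows (at least two books).
#' @return A list of class `corpus_profile`: `features` (tibble with
#'   columns `feature`, `mean`, `sd`, `sem`), `n_books`, and
#'   `n_books_negative_aap`.
#' @export
aggregate_corpus <- function(profiles) {
  if (!is.data.frame(profiles) || nrow(profiles) < 2L) {
    abort_sb("corpus aggregation needs at least two book profiles",
             "sentibook_aggregation_error")
  }
  rows <- lapply(PROFILE_FEATURES, function(f) {
    x <- profiles[[f]]
    x <- x[is.finite(x)]
    mss <- mean_sd_sem(x)
    tibble::tibble(feature = f, mean = mss[[1L]], sd = mss[[2L]],
                   sem = mss[[3L]], n_books = length(x))
  })
  structure(
    list(
      features = do.call(rbind, rows),
      n_books = nrow(profiles),
      n_books_negative_aap = sum(profiles$aap < 0, na.rm = TRUE)
    ),
    class = "corpus_profile"
  )
}

#' @export
print.corpus_profile <- function(x, ...) {
  cat(sprintf("<corpus_profile> %d books (%d with negative overall AAP)\n",
              x$n_books, x$n_books_negative_aap))
  print(x$features, n = nrow(x$features))
  invisible(x)
}
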