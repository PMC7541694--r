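# Synthetic data with planted structure: an embedding space with a known
# valence axis, corpora with a controllable positivity bias, and ratings
# generated from a logistic response curve. Everything is a pure function of
# the spec (same seed, identical output).

# Alphabetic ids ("aaaa", "aaab", ...) so every generated word survives the
# alphabetic tokenizer.
alpha_id <- function(i, width = 4L) {
  vapply(i, function(k) {
    k <- k - 1L
    chars <- character(width)
    for (j in seq_len(width)) {
      chars[[width - j + 1L]] <- letters[[k %% 26L + 1L]]
      k <- k %/% 26L
    }
    paste(chars, collapse = "")
  }, character(1))
}

FUNCTION_WORDS <- c("the", "and", "a", "to", "of", "in", "it", "was",
                    "he", "she")

#' Specification of the synthetic study conditions
#'
#' Bundles every parameter of the generators. Generation is a pure function
#' of the spec: the same seed yields byte-identical output.
#'
#' @param dimension Embedding dimension (>= 2).
#' @param vocab_size Total vocabulary size, including the 120 AAP labels,
#'   the 6 emotion labels and the function words.
#' @param positive_proportion Probability `p` that a content-word slot in a
#'   generated book draws from the positive pool (in `[0, 1]`; the
#'   analytic PNR oracle [expected_pnr()] requires the open interval).
#' @param affect_strength Projection of pool-word vectors onto the planted
#'   valence axis (>= 0).
#' @param noise_sd Standard deviation of the isotropic Gaussian noise added
#'   to pool-word vectors.
#' @param n_books,sentences_per_book,words_per_sentence Corpus shape
#'   (content words per sentence; function words are interleaved on top,
#'   one per three content words).
#' @param seed Integer seed controlling all randomness.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(dimension = 50L,
                           vocab_size = 1000L,
                           positive_proportion = 0.5,
                           affect_strength = 1.0,
                           noise_sd = 0.2,
                           n_books = 3L,
                           sentences_per_book = 100L,
                           words_per_sentence = 8L,
                           seed = 1234L) {
  if (!is_count(dimension) || dimension < 2L) {
    abort_sb("`dimension` must be an integer >= 2", "sentibook_spec_error")
  }
  for (arg in list(vocab_size = vocab_size, n_books = n_books,
                   sentences_per_book = sentences_per_book,
                   words_per_sentence = words_per_sentence)) {
    if (!is_count(arg)) {
      abort_sb("all synthetic counts must be positive integers",
               "sentibook_spec_error")
    }
  }
  if (!is_scalar_number(positive_proportion) ||
      positive_proportion < 0 || positive_proportion > 1) {
    abort_sb("`positive_proportion` must lie in [0, 1]",
             "sentibook_spec_error")
  }
  if (!is_scalar_number(affect_strength) || affect_strength < 0 ||
      !is_scalar_number(noise_sd) || noise_sd < 0) {
    abort_sb("`affect_strength` and `noise_sd` must be >= 0",
             "sentibook_spec_error")
  }
  n_reserved <- 120L + 6L + length(FUNCTION_WORDS)
  if (vocab_size < n_reserved + 8L) {
    abort_sb(
      sprintf("`vocab_size` must be at least %d to host labels and pools",
              n_reserved + 8L),
      "sentibook_spec_error"
    )
  }
  structure(
    list(
      dimension = as.integer(dimension),
      vocab_size = as.integer(vocab_size),
      positive_proportion = positive_proportion,
      affect_strength = affect_strength,
      noise_sd = noise_sd,
      n_books = as.integer(n_books),
      sentences_per_book = as.integer(sentences_per_book),
      words_per_sentence = as.integer(words_per_sentence),
      function_word_rate = 3L,  # one function word per 3 content words
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate an embedding space with a planted valence axis
#'
#' The first coordinate axis is the valence axis. Positive-pool words sit
#' at `+affect_strength * axis` plus isotropic Gaussian noise
#' (`sd = noise_sd`); negative-pool words are mirrored at
#' `-affect_strength * axis`. The 60 positive AAP labels sit near `+axis`
#' and each negative label is the exact reflection of a positive label
#' through the hyperplane orthogonal to the axis, so reflecting a word
#' vector negates its AAP exactly. The six emotion labels are fixed random
#' directions. Pool words carry NOUN/VERB/ADJ/ADV round-robin in the
#' bundled lexicon; function words are OTHER.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_space`: `spec`, `table`
#'   ([word_vector_table()]), `labels` ([label_config()]), `lexicon`,
#'   `tagger`, `pools` (character vectors `positive`, `negative`), `axis`.
#' @export
generate_embedding_space <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d <- spec$dimension
  axis <- c(1, rep(0, d - 1L))
  with_seed(spec$seed, {
    n_lab <- 60L
    pos_lab_names <- paste0("plab", alpha_id(seq_len(n_lab)))
    neg_lab_names <- paste0("nlab", alpha_id(seq_len(n_lab)))
    pos_lab <- matrix(rnorm(n_lab * d, sd = 0.1), nrow = n_lab)
    pos_lab[, 1L] <- pos_lab[, 1L] + 1
    neg_lab <- pos_lab
    neg_lab[, 1L] <- -neg_lab[, 1L]  # exact mirror through the axis plane
    emo_lab <- matrix(rnorm(6L * d), nrow = 6L)
    n_fun <- length(FUNCTION_WORDS)
    fun_vec <- matrix(rnorm(n_fun * d, sd = max(spec$noise_sd, 0.05)),
                      nrow = n_fun)
    n_pool <- spec$vocab_size - 2L * n_lab - 6L - n_fun
    n_pos <- n_pool %/% 2L
    n_neg <- n_pool - n_pos
    pos_names <- paste0("pw", alpha_id(seq_len(n_pos)))
    neg_names <- paste0("nw", alpha_id(seq_len(n_neg)))
    pos_vec <- matrix(rnorm(n_pos * d, sd = spec$noise_sd), nrow = n_pos)
    pos_vec[, 1L] <- pos_vec[, 1L] + spec$affect_strength
    neg_vec <- matrix(rnorm(n_neg * d, sd = spec$noise_sd), nrow = n_neg)
    neg_vec[, 1L] <- neg_vec[, 1L] - spec$affect_strength
    vectors <- rbind(pos_lab, neg_lab, emo_lab, fun_vec, pos_vec, neg_vec)
    rownames(vectors) <- c(pos_lab_names, neg_lab_names, EMOTION_NAMES,
                           FUNCTION_WORDS, pos_names, neg_names)
    zero <- rowSums(vectors != 0) == 0L
    if (any(zero)) vectors[zero, 1L] <- 1e-8  # astronomically unlikely
    table <- word_vector_table(vectors, case_policy = "lowercase")
    labels <- label_config(
      positive_labels = pos_lab_names,
      negative_labels = neg_lab_names,
      emotion_labels = stats::setNames(EMOTION_NAMES, EMOTION_NAMES)
    )
    pool_names <- c(pos_names, neg_names)
    lexicon <- data.frame(
      surface = c(pool_names, FUNCTION_WORDS),
      lemma = c(pool_names, FUNCTION_WORDS),
      pos_class = c(rep_len(CONTENT_POS, n_pos), rep_len(CONTENT_POS, n_neg),
                    rep("OTHER", n_fun)),
      stringsAsFactors = FALSE
    )
    structure(
      list(
        spec = spec,
        table = table,
        labels = labels,
        lexicon = lexicon,
        tagger = lexicon_tagger(lexicon),
        pools = list(positive = pos_names, negative = neg_names),
        axis = axis
      ),
      class = "synthetic_space"
    )
  })
}

# Sentence strings for one synthetic book (content words + interleaved
# function words, terminated by a period).
synthetic_sentences <- function(spec, space) {
  p <- spec$positive_proportion
  rate <- spec$function_word_rate
  vapply(seq_len(spec$sentences_per_book), function(s) {
    take_pos <- runif(spec$words_per_sentence) < p
    words <- ifelse(
      take_pos,
      sample(space$pools$positive, spec$words_per_sentence, replace = TRUE),
      sample(space$pools$negative, spec$words_per_sentence, replace = TRUE)
    )
    out <- character(0)
    for (i in seq_along(words)) {
      out <- c(out, words[[i]])
      if (i %% rate == 0L && i < length(words)) {
        out <- c(out, sample(FUNCTION_WORDS, 1L))
      }
    }
    paste0(paste(out, collapse = " "), ".")
  }, character(1))
}

#' Generate a synthetic book
#'
#' Every content-word slot draws from the positive pool with probability
#' `positive_proportion`, otherwise from the negative pool; one function
#' word is interleaved per three content words so content-word filtering is
#' exercised. The text is passed through the regular ingestion path
#' (segmentation + lexicon tagging), so the returned document is exactly
#' what the pipeline would build from the written file.
#'
#' @param spec A [synthetic_spec()].
#' @param space The [generate_embedding_space()] output for the same spec.
#' @param book_index 1-based index; each book gets its own sub-seed
#'   (`seed + book_index`).
#' @return A [book_document()].
#' @export
generate_book <- function(spec, space, book_index = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(space, "synthetic_space"))
  text <- with_seed(spec$seed + book_index, {
    paste(synthetic_sentences(spec, space), collapse = " ")
  })
  book_document(
    text, space$tagger,
    book_id = sprintf("book%03d", book_index),
    title = sprintf("Synthetic book %d (p = %.2f)",
                    book_index, spec$positive_proportion),
    author = "synthetic"
  )
}

#' Analytic PNR oracle for the planted bias
#'
#' When content words are drawn positive with probability `p` and the
#' affect signal dominates the noise, the expected ratio of positive to
#' negative words is `p / (1 - p)`.
#'
#' @param p Planted positive proportion, strictly between 0 and 1.
#' @return `p / (1 - p)`.
#' @export
expected_pnr <- function(p) {
  if (!is_scalar_number(p) || p <= 0 || p >= 1) {
    abort_sb("expected PNR is undefined unless 0 < p < 1",
             "sentibook_spec_error")
  }
  p / (1 - p)
}

# Moments of clip(Z, L, U) for Z ~ N(mu, sd^2) (censored normal).
censored_normal_moments <- function(mu, sd, L, U) {
  a <- (L - mu) / sd
  b <- (U - mu) / sd
  p_lo <- stats::pnorm(a)
  p_hi <- 1 - stats::pnorm(b)
  dphi <- stats::pnorm(b) - stats::pnorm(a)
  # truncated-normal mean/variance on (L, U); guard empty interior
  tm <- ifelse(dphi > 0,
               mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
                 pmax(dphi, .Machine$double.xmin),
               0)
  tv <- ifelse(dphi > 0,
               sd^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) /
                         pmax(dphi, .Machine$double.xmin) -
                         ((stats::dnorm(a) - stats::dnorm(b)) /
                            pmax(dphi, .Machine$double.xmin))^2),
               0)
  m1 <- L * p_lo + U * p_hi + dphi * tm
  m2 <- L^2 * p_lo + U^2 * p_hi + dphi * (tv + tm^2)
  list(mean = m1, var = pmax(m2 - m1^2, 0))
}

# Population R-squared of the clipped rating: variance of the conditional
# mean over total variance, for rating_i = clip(signal_i + noise, L, U).
clipped_population_r2 <- function(signal, noise_sd, L, U) {
  mom <- censored_normal_moments(signal, noise_sd, L, U)
  explained <- mean((mom$mean - mean(mom$mean))^2)
  total <- explained + mean(mom$var)
  if (total == 0) return(1)
  explained / total
}

# Noise sd such that the population R-squared of the clipped ratings hits
# the target; accounts for the censoring at the scale ends (which would
# otherwise inflate the realized R-squared).
calibrate_rating_noise <- function(signal, target_r2, L, U) {
  span <- U - L
  f <- function(s) clipped_population_r2(signal, s, L, U) - target_r2
  stats::uniroot(f, interval = c(1e-8 * span, 100 * span), tol = 1e-10)$root
}

#' Generate synthetic word-valence ratings
#'
#' Samples words from the pools, computes their AAP in the synthetic
#' space, pushes it through a 4-parameter logistic response curve, adds
#' Gaussian rating noise, and clips to the rating scale. With
#' `target_r2` given, the noise sd is calibrated so that the population
#' R-squared of the clipped ratings — the variance of the conditional mean
#' rating over the total rating variance, computed from censored-normal
#' moments — equals the target. (The naive pre-clipping ratio
#' `var(signal) / (var(signal) + sd^2)` would understate the realized
#' R-squared, because censoring at the scale ends truncates the noise.)
#'
#' @param spec A [synthetic_spec()].
#' @param space Matching [generate_embedding_space()] output.
#' @param curve Named numeric 4PL parameters `lower`, `upper`, `slope`,
#'   `xmid`; asymptotes must lie inside the rating scale.
#' @param noise_sd Rating noise sd; ignored when `target_r2` is given.
#' @param target_r2 Optional population R-squared to calibrate the noise to.
#' @param n_words Number of rated words (default 90).
#' @param scale Rating scale bounds (default the 5-point scale `c(1, 5)`).
#' @param seed_offset Added to `spec$seed` for this draw, so rating
#'   replicates can vary while the space stays fixed.
#' @return A list of class `rating_dataset`: `data` (tibble `word`,
#'   `rating`), `aap`, `true_parameters`, `noise_sd`, `scale_min`,
#'   `scale_max`.
#' @export
generate_ratings <- function(spec, space,
                             curve = c(lower = 1.5, upper = 4.5,
                                       slope = 2, xmid = 0),
                             noise_sd = 0.5, target_r2 = NULL,
                             n_words = 90L, scale = c(1, 5),
                             seed_offset = 101L) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(space, "synthetic_space"))
  need <- c("lower", "upper", "slope", "xmid")
  if (!all(need %in% names(curve))) {
    abort_sb("`curve` needs named parameters lower, upper, slope, xmid",
             "sentibook_spec_error")
  }
  if (curve[["lower"]] < scale[[1L]] || curve[["upper"]] > scale[[2L]]) {
    abort_sb("curve asymptotes must lie inside the rating scale",
             "sentibook_spec_error")
  }
  lm <- label_matrices(space$labels, space$table)
  pool <- c(space$pools$positive, space$pools$negative)
  if (n_words > length(pool)) {
    message(sprintf("only %d pool words available; rating %d words instead of %d",
                    length(pool), length(pool), n_words))
    n_words <- length(pool)
  }
  with_seed(spec$seed + seed_offset, {
    words <- sample(pool, n_words)
    u <- space$table$vectors[words, , drop = FALSE]
    u <- u / sqrt(rowSums(u * u))
    aap <- rowMeans(u %*% t(lm$positive)) - rowMeans(u %*% t(lm$negative))
    signal <- fpl(aap, curve[["lower"]], curve[["upper"]],
                  curve[["slope"]], curve[["xmid"]])
    if (!is.null(target_r2)) {
      if (!is_scalar_number(target_r2) || target_r2 <= 0 || target_r2 >= 1) {
        abort_sb("`target_r2` must lie strictly between 0 and 1",
                 "sentibook_spec_error")
      }
      noise_sd <- calibrate_rating_noise(signal, target_r2,
                                         scale[[1L]], scale[[2L]])
    }
    ratings <- signal + rnorm(n_words, sd = noise_sd)
    ratings <- pmin(pmax(ratings, scale[[1L]]), scale[[2L]])
    structure(
      list(
        data = tibble::tibble(word = words, rating = ratings),
        aap = stats::setNames(aap, words),
        true_parameters = curve[need],
        noise_sd = noise_sd,
        scale_min = scale[[1L]],
        scale_max = scale[[2L]]
      ),
      class = "rating_dataset"
    )
  })
}

#' Write a complete fixture bundle to disk
#'
#' Materializes a synthetic study as plain-text files consumable by
#' [run_pipeline()] (and the command-line wrapper) unchanged: the `.vec`
#' embedding file, the JSON label config, the tagger lexicon TSV, the
#' corpus manifest TSV plus one text file per book, a ratings TSV, and a
#' `spec.json` with the generator parameters.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_fixture_bundle <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(file.path(dir, "books"), recursive = TRUE, showWarnings = FALSE)
  space <- generate_embedding_space(spec)
  tab <- space$table
  vec_path <- file.path(dir, "vectors.vec")
  con <- file(vec_path, open = "wb")
  writeLines(sprintf("%d %d", length(tab$vocabulary), tab$dimension), con)
  writeLines(
    paste(tab$vocabulary,
          apply(tab$vectors, 1L, function(v) {
            paste(sprintf("%.17g", v), collapse = " ")
          })),
    con
  )
  close(con)
  labels_path <- file.path(dir, "labels.json")
  jsonlite::write_json(
    list(
      positive_labels = space$labels$positive_labels,
      negative_labels = space$labels$negative_labels,
      emotion_labels = as.list(space$labels$emotion_labels)
    ),
    labels_path, auto_unbox = TRUE, pretty = TRUE
  )
  lex_path <- file.path(dir, "lexicon.tsv")
  write.table(space$lexicon, lex_path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  book_paths <- character(spec$n_books)
  ids <- character(spec$n_books)
  titles <- character(spec$n_books)
  for (b in seq_len(spec$n_books)) {
    ids[[b]] <- sprintf("book%03d", b)
    titles[[b]] <- sprintf("Synthetic book %d (p = %.2f)",
                           b, spec$positive_proportion)
    book_paths[[b]] <- file.path("books", paste0(ids[[b]], ".txt"))
    text <- with_seed(spec$seed + b, {
      paste(synthetic_sentences(spec, space), collapse = " ")
    })
    writeLines(text, file.path(dir, book_paths[[b]]), useBytes = TRUE)
  }
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(
    data.frame(book_id = ids, path = book_paths, title = titles,
               author = "synthetic", stringsAsFactors = FALSE),
    manifest_path, sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  ratings <- generate_ratings(spec, space)
  ratings_path <- file.path(dir, "ratings.tsv")
  write.table(as.data.frame(ratings$data), ratings_path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  spec_path <- file.path(dir, "spec.json")
  jsonlite::write_json(unclass(spec), spec_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(
    dir = dir, vectors = vec_path, labels = labels_path,
    lexicon = lex_path, manifest = manifest_path,
    books = file.path(dir, book_paths), ratings = ratings_path,
    spec = spec_path
  ))
}
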