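# Synthetic generators: determinism, planted structure, analytic oracles.

test_that("generation is a pure function of the spec", {
  spec <- synthetic_spec(vocab_size = 200, sentences_per_book = 10, seed = 5)
  s1 <- generate_embedding_space(spec)
  s2 <- generate_embedding_space(spec)
  expect_identical(s1$table$vectors, s2$table$vectors)
  expect_identical(s1$lexicon, s2$lexicon)
  b1 <- generate_book(spec, s1, 1)
  b2 <- generate_book(spec, s2, 1)
  expect_identical(b1, b2)
  # different books from the same spec differ
  b3 <- generate_book(spec, s1, 2)
  expect_false(identical(b1$sentences, b3$sentences))
})

test_that("spec validation rejects impossible parameters", {
  expect_error(synthetic_spec(dimension = 1), class = "sentibook_spec_error")
  expect_error(synthetic_spec(vocab_size = 100),  # cannot host 126 labels
               class = "sentibook_spec_error")
  expect_error(synthetic_spec(positive_proportion = 1.2),
               class = "sentibook_spec_error")
  expect_error(synthetic_spec(noise_sd = -1), class = "sentibook_spec_error")
})

test_that("labels are resolvable and exactly mirror-symmetric", {
  spec <- synthetic_spec(vocab_size = 200, seed = 8)
  space <- generate_embedding_space(spec)
  expect_true(validate_labels(space$labels, space$table)$ok)
  pos <- space$table$vectors[space$labels$positive_labels, ]
  neg <- space$table$vectors[space$labels$negative_labels, ]
  expect_equal(unname(neg[, 1]), unname(-pos[, 1]))
  expect_equal(unname(neg[, -1]), unname(pos[, -1]))
})

test_that("a word on the axis with single axis labels has AAP 2", {
  m <- rbind(good = c(1, 0), bad = c(-1, 0), word = c(1, 0),
             anger = c(0, 1), disgust = c(1, 1), fear = c(-1, 1),
             happiness = c(1, 2), sadness = c(-2, 1), surprise = c(2, 1))
  tab <- word_vector_table(m)
  labels <- label_config("good", "bad",
                         c(anger = "anger", disgust = "disgust",
                           fear = "fear", happiness = "happiness",
                           sadness = "sadness", surprise = "surprise"))
  expect_equal(word_aap("word", labels, tab), 2)
})

test_that("with zero affect strength the vocabulary AAP centers on zero", {
  spec <- synthetic_spec(affect_strength = 0, vocab_size = 500, seed = 31)
  space <- generate_embedding_space(spec)
  words <- c(space$pools$positive, space$pools$negative)
  u <- space$table$vectors[words, ]
  u <- u / sqrt(rowSums(u * u))
  lab <- function(ws) {
    m <- space$table$vectors[ws, ]
    m / sqrt(rowSums(m * m))
  }
  aaps <- rowMeans(u %*% t(lab(space$labels$positive_labels))) -
    rowMeans(u %*% t(lab(space$labels$negative_labels)))
  expect_lt(abs(mean(aaps)), 3 * sd(aaps) / sqrt(length(aaps)))
})

test_that("the analytic PNR oracle is p/(1-p)", {
  expect_equal(expected_pnr(0.5), 1.0)
  expect_equal(expected_pnr(0.7), 7 / 3)
  expect_equal(expected_pnr(0.6), 1.5)
  expect_error(expected_pnr(0), class = "sentibook_spec_error")
  expect_error(expected_pnr(1), class = "sentibook_spec_error")
})

test_that("p = 1 produces an all-positive book with flagged infinite PNR", {
  spec <- synthetic_spec(positive_proportion = 1, vocab_size = 200,
                         sentences_per_book = 10, seed = 13)
  space <- generate_embedding_space(spec)
  book <- generate_book(spec, space, 1)
  scored <- score_book(book, space$labels, space$table)
  expect_equal(sum(scored$n_negative), 0L)
  expect_warning(
    prof <- aggregate_book(scored, compute_corpus_stats(book)),
    "infinite"
  )
  expect_true(is.infinite(prof$pnr))
})

test_that("books interleave function words that the filter removes", {
  spec <- synthetic_spec(vocab_size = 200, sentences_per_book = 5, seed = 2)
  space <- generate_embedding_space(spec)
  book <- generate_book(spec, space, 1)
  toks <- book$sentences[[1]]$tokens
  expect_gt(nrow(toks), nrow(filter_content_words(toks)))
  # 8 content words + 2 interleaved function words + final period
  expect_equal(nrow(filter_content_words(toks)), spec$words_per_sentence)
})

test_that("words planted near the fear label score fear highest", {
  spec <- synthetic_spec(vocab_size = 200, seed = 41)
  space <- generate_embedding_space(spec)
  fear_vec <- space$table$vectors["fear", ]
  set.seed(42)
  m <- space$table$vectors
  for (i in 1:5) {
    m <- rbind(m, fear_vec + rnorm(spec$dimension, sd = 0.1))
    rownames(m)[nrow(m)] <- paste0("fearish", letters[i])
  }
  tab <- word_vector_table(m)
  for (i in 1:5) {
    scores <- vapply(space$labels$emotion_labels, function(lab) {
      word_emotion(paste0("fearish", letters[i]), lab, tab)
    }, numeric(1))
    expect_equal(names(which.max(scores)), "fear")
  }
})

test_that("generated ratings live on the scale and recover noise-free curves", {
  spec <- synthetic_spec(vocab_size = 400, seed = 61)
  space <- generate_embedding_space(spec)
  r <- generate_ratings(spec, space, noise_sd = 0.4)
  expect_equal(nrow(r$data), 90)
  expect_true(all(r$data$rating >= 1 & r$data$rating <= 5))

  r0 <- generate_ratings(spec, space, noise_sd = 0)
  fit <- fit_valence_curve(r0$aap, r0$data$rating, "logistic")
  expect_gte(fit$r2, 0.999)
  for (p in names(r0$true_parameters)) {
    expect_equal(unname(fit$parameters[[p]]),
                 unname(r0$true_parameters[[p]]), tolerance = 1e-6)
  }
})

test_that("noise calibration hits the requested population R2 after clipping", {
  spec <- synthetic_spec(vocab_size = 400, seed = 62)
  space <- generate_embedding_space(spec)
  r <- generate_ratings(spec, space, target_r2 = 0.68)
  expect_gt(r$noise_sd, 0)
  # large-sample check of the censored-moment calibration: regenerate the
  # clipped response many times and compare realized R2 of the true curve
  set.seed(99)
  sig <- r$aap
  curve <- r$true_parameters
  signal <- curve[["lower"]] + (curve[["upper"]] - curve[["lower"]]) /
    (1 + exp(-curve[["slope"]] * (sig - curve[["xmid"]])))
  reps <- replicate(400, {
    y <- pmin(pmax(signal + rnorm(length(signal), sd = r$noise_sd), 1), 5)
    pred <- pmin(pmax(signal, 1), 5)
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  })
  expect_lt(abs(mean(reps) - 0.68), 0.05)
})

test_that("the fixture bundle is consumable and faithful", {
  dir <- tempfile("bundle")
  spec <- synthetic_spec(vocab_size = 200, n_books = 2,
                         sentences_per_book = 8, seed = 77)
  paths <- write_fixture_bundle(spec, dir)
  expect_true(all(file.exists(unlist(
    paths[c("vectors", "labels", "lexicon", "manifest", "ratings")]))))
  tab <- read_word_vectors(paths$vectors)
  space <- generate_embedding_space(spec)
  expect_equal(tab$vectors[space$table$vocabulary, ],
               space$table$vectors)   # %.17g round-trips exactly
  labels <- read_label_config(paths$labels)
  expect_true(validate_labels(labels, tab)$ok)
  books <- read_corpus(paths$manifest, lexicon_tagger(
    read_tagger_lexicon(paths$lexicon)))
  expect_length(books, 2)
  expect_identical(books[[1]]$sentences,
                   generate_book(spec, space, 1)$sentences)
})
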