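# Word AAP, emotion scores, sentence scoring, book and corpus aggregation.

test_that("word AAP matches hand-computed toy cases", {
  # positive label (1,0), negative (-1,0): word (1,0) -> 1 - (-1) = 2
  tab <- toy_table()
  labels <- toy_labels()
  expect_equal(word_aap("pl1", labels, tab), 2)
  expect_equal(word_aap("sun", labels, tab), 0)  # (0,1) orthogonal to both

  # positive labels {(1,0),(0,1)}, negative {(-1,0)}, word (1,0) -> 1.5
  m <- rbind(toy_vectors(), p2 = c(0, 1), w = c(1, 0))
  tab2 <- word_vector_table(m)
  labels2 <- toy_labels(positive = c("pl1", "p2"))
  expect_equal(word_aap("w", labels2, tab2), (1 + 0) / 2 - (-1))
})

test_that("OOV words are not scorable, not errors", {
  expect_true(is.na(word_aap("zzqx", toy_labels(), toy_table())))
  expect_true(is.na(word_emotion("zzqx", "happiness", toy_table())))
})

test_that("word emotion is the cosine with the single label", {
  tab <- toy_table()
  expect_equal(word_emotion("sun", "anger", tab), 1)    # both (0,1)
  expect_equal(word_emotion("pl1", "anger", tab), 0)    # orthogonal
  expect_equal(word_emotion("cat", "dog", tab), 0.96)   # (3,4) vs (4,3)
  expect_error(word_emotion("cat", "zzqx", tab),
               class = "sentibook_label_error")
})

test_that("sentence scoring averages scorable content words and counts signs", {
  # three content words with AAP 0.2, -0.1, 0.5 under toy labels
  m <- rbind(toy_vectors(),
             wa = word_with_aap(0.2),
             wb = word_with_aap(-0.1),
             wc = word_with_aap(0.5))
  tab <- word_vector_table(m)
  toks <- tokens_of(c("the", "wa", "wb", "wc", "!"),
                    c("OTHER", "NOUN", "VERB", "ADJ", "OTHER"))
  sa <- score_sentence(list(index = 0L, tokens = toks), toy_labels(), tab)
  expect_equal(sa$aap, 0.6 / 3)
  expect_equal(sa$n_scored, 3L)
  expect_equal(sa$n_positive, 2L)
  expect_equal(sa$n_negative, 1L)
  expect_equal(sa$aap_noun, 0.2)
  expect_equal(sa$aap_verb, -0.1)
  expect_equal(sa$aap_adjective, 0.5)
  expect_true(is.na(sa$aap_adverb))  # no adverb in the sentence
})

test_that("a sentence with no content words is all-undefined, flagged by n_scored", {
  toks <- tokens_of(c("the", "!"), c("OTHER", "OTHER"))
  sa <- score_sentence(list(index = 3L, tokens = toks),
                       toy_labels(), toy_table())
  expect_equal(sa$n_scored, 0L)
  expect_true(is.na(sa$aap))
  expect_true(all(is.na(unlist(
    sa[, c("aap_noun", "aap_verb", "aap_adjective", "aap_adverb",
           "anger", "disgust", "fear", "happiness", "sadness", "surprise")]
  ))))
  expect_equal(sa$n_positive + sa$n_negative, 0L)
})

test_that("words with AAP exactly zero count as neither positive nor negative", {
  m <- rbind(toy_vectors(), w0 = c(0, 1))  # AAP exactly 0
  tab <- word_vector_table(m)
  sa <- score_sentence(
    list(index = 0L, tokens = tokens_of("w0", "NOUN")), toy_labels(), tab)
  expect_equal(sa$n_scored, 1L)
  expect_equal(sa$n_positive, 0L)
  expect_equal(sa$n_negative, 0L)
  expect_lte(sa$n_positive + sa$n_negative, sa$n_scored)
})

fake_stats <- function(n_sentences) {
  tibble::tibble(n_sentences = n_sentences,
                 mean_words_per_sentence = 5, n_tokens = 5L * n_sentences,
                 n_types = 4L, mean_word_length = 3,
                 type_token_ratio = 0.5)
}

fake_sentences <- function(aap, n_positive, n_negative) {
  n <- length(aap)
  tibble::tibble(
    sentence_index = seq_len(n) - 1L,
    n_content = 5L, n_scored = 5L,
    aap = aap, aap_noun = aap, aap_verb = NA_real_,
    aap_adjective = NA_real_, aap_adverb = NA_real_,
    anger = aap, disgust = aap, fear = aap, happiness = aap,
    sadness = aap, surprise = aap,
    n_positive = n_positive, n_negative = n_negative
  )
}

test_that("book aggregation averages sentences and sums PNR counts", {
  sa <- fake_sentences(c(0.1, 0.3), c(4L, 2L), c(2L, 1L))
  prof <- aggregate_book(sa, fake_stats(2L), book_id = "b1")
  expect_equal(prof$aap, 0.2)
  expect_equal(prof$pnr, 6 / 3)  # (4+2)/(2+1)
  expect_equal(prof$aap_sd, sd(c(0.1, 0.3)))
  expect_equal(prof$aap_sem, sd(c(0.1, 0.3)) / sqrt(2))

  # mean mode averages per-sentence ratios instead
  prof_mean <- aggregate_book(sa, fake_stats(2L), pnr_mode = "mean")
  expect_equal(prof_mean$pnr, mean(c(4 / 2, 2 / 1)))
})

test_that("a book without negative words gets an infinite, flagged PNR", {
  sa <- fake_sentences(c(0.2, 0.4), c(3L, 2L), c(0L, 0L))
  expect_warning(prof <- aggregate_book(sa, fake_stats(2L)), "infinite")
  expect_true(is.infinite(prof$pnr))
})

test_that("a book with no scorable sentence is a scoring error", {
  sa <- fake_sentences(c(NA_real_, NA_real_), c(0L, 0L), c(0L, 0L))
  expect_error(aggregate_book(sa, fake_stats(2L)),
               class = "sentibook_scoring_error")
})

test_that("book AAP equals the mean of defined sentence AAPs exactly", {
  set.seed(11)
  aaps <- c(rnorm(20, sd = 0.3), NA_real_)
  sa <- fake_sentences(aaps, rep(1L, 21), rep(1L, 21))
  prof <- aggregate_book(sa, fake_stats(21L))
  expect_identical(prof$aap, mean(aaps, na.rm = TRUE))
})

test_that("corpus aggregation reports mean/sd/sem and the negative-AAP count", {
  sa1 <- fake_sentences(c(0.1, 0.1), c(1L, 1L), c(1L, 1L))
  sa2 <- fake_sentences(c(0.3, 0.3), c(1L, 1L), c(1L, 1L))
  p1 <- aggregate_book(sa1, fake_stats(2L), book_id = "a")
  p2 <- aggregate_book(sa2, fake_stats(2L), book_id = "b")
  corp <- aggregate_corpus(rbind(p1, p2))
  aap_row <- corp$features[corp$features$feature == "aap", ]
  expect_equal(aap_row$mean, 0.2)
  expect_equal(aap_row$sd, sd(c(0.1, 0.3)), tolerance = 1e-12)
  expect_equal(corp$n_books_negative_aap, 0)

  # identical books -> sem 0
  corp2 <- aggregate_corpus(rbind(p1, p1))
  expect_equal(corp2$features$sem[corp2$features$feature == "aap"], 0)

  # a negative book is counted
  sa3 <- fake_sentences(c(-0.2, -0.4), c(0L, 0L), c(2L, 2L))
  p3 <- aggregate_book(sa3, fake_stats(2L), book_id = "c")
  corp3 <- aggregate_corpus(rbind(p1, p3))
  expect_equal(corp3$n_books_negative_aap, 1)

  expect_error(aggregate_corpus(p1), class = "sentibook_aggregation_error")
})

test_that("vectorized scoring equals the naive reference on a synthetic book", {
  spec <- synthetic_spec(vocab_size = 200, sentences_per_book = 12,
                         words_per_sentence = 5, seed = 303)
  space <- generate_embedding_space(spec)
  book <- generate_book(spec, space, 1)
  scored <- score_book(book, space$labels, space$table)
  for (i in seq_along(book$sentences)) {
    ref <- ref_score_sentence(book$sentences[[i]]$tokens,
                              space$labels, space$table)
    expect_equal(scored$aap[[i]], ref$aap, tolerance = 1e-10)
    expect_equal(scored$n_positive[[i]], ref$n_positive)
    expect_equal(scored$n_negative[[i]], ref$n_negative)
    expect_equal(unname(unlist(scored[i, c("anger", "disgust", "fear",
                                           "happiness", "sadness",
                                           "surprise")])),
                 unname(ref$emotions), tolerance = 1e-10)
  }
})

test_that("word AAP stays in [-2,2] and emotions in [-1,1] on synthetic vocab", {
  spec <- synthetic_spec(vocab_size = 300, seed = 99)
  space <- generate_embedding_space(spec)
  words <- c(space$pools$positive[1:30], space$pools$negative[1:30])
  for (w in words) {
    a <- word_aap(w, space$labels, space$table)
    expect_gte(a, -2)
    expect_lte(a, 2)
  }
  for (w in words[1:10]) {
    for (e in names(space$labels$emotion_labels)) {
      s <- word_emotion(w, space$labels$emotion_labels[[e]], space$table)
      expect_gte(s, -1)
      expect_lte(s, 1)
    }
  }
})

test_that("reflecting word vectors through the valence plane negates AAP and inverts PNR", {
  spec <- synthetic_spec(vocab_size = 250, sentences_per_book = 20,
                         positive_proportion = 0.7, seed = 17)
  space <- generate_embedding_space(spec)
  book <- generate_book(spec, space, 1)
  scored <- score_book(book, space$labels, space$table)

  refl <- space$table$vectors
  pool <- c(space$pools$positive, space$pools$negative)
  refl[rownames(refl) %in% pool, 1] <- -refl[rownames(refl) %in% pool, 1]
  tab_r <- word_vector_table(refl)
  scored_r <- score_book(book, space$labels, tab_r)

  expect_equal(scored_r$aap, -scored$aap, tolerance = 1e-12)
  expect_equal(scored_r$n_positive, scored$n_negative)
  expect_equal(scored_r$n_negative, scored$n_positive)

  st <- compute_corpus_stats(book)
  p1 <- aggregate_book(scored, st, book_id = "orig")
  p2 <- aggregate_book(scored_r, st, book_id = "refl")
  expect_equal(p2$pnr, 1 / p1$pnr, tolerance = 1e-12)
})

test_that("mean AAP and PNR increase with the planted positive proportion", {
  profs <- lapply(c(0.3, 0.5, 0.7), function(p) {
    spec <- synthetic_spec(positive_proportion = p, vocab_size = 300,
                           sentences_per_book = 60, seed = 505)
    space <- generate_embedding_space(spec)
    book <- generate_book(spec, space, 1)
    aggregate_book(score_book(book, space$labels, space$table),
                   compute_corpus_stats(book), book_id = sprintf("p%.1f", p))
  })
  aaps <- vapply(profs, function(p) p$aap, numeric(1))
  pnrs <- vapply(profs, function(p) p$pnr, numeric(1))
  expect_true(all(diff(aaps) > 0))
  expect_true(all(diff(pnrs) > 0))
})
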