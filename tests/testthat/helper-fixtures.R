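# Shared fixtures: a tiny hand-built embedding space, a fixed tagger
# lexicon, and a naive loop-based reference implementation of the scoring
# pipeline (independent oracle for the vectorized path).

# 2-dim toy space: positive label on +x, negative label on -x, so a unit
# word (x, y) has AAP = 2x. Six emotion labels at fixed directions.
toy_vectors <- function() {
  m <- rbind(
    pl1 = c(1, 0),
    nl1 = c(-1, 0),
    anger = c(0, 1),
    disgust = c(1, 1),
    fear = c(-1, 1),
    happiness = c(1, 0.5),
    sadness = c(-1, -0.5),
    surprise = c(0.5, 1),
    cat = c(3, 4),
    dog = c(4, 3),
    sun = c(0, 1),
    run = c(0.5, 0.5)
  )
  m
}

toy_table <- function() word_vector_table(toy_vectors())

toy_labels <- function(positive = "pl1", negative = "nl1") {
  label_config(
    positive_labels = positive,
    negative_labels = negative,
    emotion_labels = c(anger = "anger", disgust = "disgust", fear = "fear",
                       happiness = "happiness", sadness = "sadness",
                       surprise = "surprise")
  )
}

toy_lexicon <- function() {
  data.frame(
    surface = c("cat", "dog", "sun", "sat", "ran", "run", "lovely", "sad",
                "quickly"),
    lemma = c("cat", "dog", "sun", "sit", "run", "run", "lovely", "sad",
              "quickly"),
    pos_class = c("NOUN", "NOUN", "NOUN", "VERB", "VERB", "VERB", "ADJ",
                  "ADJ", "ADV"),
    stringsAsFactors = FALSE
  )
}

toy_tagger <- function() lexicon_tagger(toy_lexicon())

# Tagged-token tibble straight from (surface, pos) pairs, lemma = surface.
tokens_of <- function(surface, pos_class, lemma = surface) {
  tibble::tibble(surface = surface, lemma = lemma, pos_class = pos_class)
}

# A unit-norm 2-dim word with prescribed AAP under the toy labels
# (pl1 = +x, nl1 = -x): AAP(x, y) = 2x for unit (x, y).
word_with_aap <- function(aap) {
  x <- aap / 2
  c(x, sqrt(1 - x^2))
}

# ---- naive loop-based reference implementation (independent oracle) ------

ref_cosine <- function(a, b) {
  num <- 0
  na <- 0
  nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[[i]] * b[[i]]
    na <- na + a[[i]]^2
    nb <- nb + b[[i]]^2
  }
  num / (sqrt(na) * sqrt(nb))
}

ref_lookup <- function(surface, lemma, table) {
  for (cand in unique(c(surface, tolower(surface), lemma, tolower(lemma)))) {
    if (cand %in% rownames(table$vectors)) {
      return(table$vectors[cand, ])
    }
  }
  NULL
}

ref_word_aap <- function(v, labels, table) {
  s_pos <- 0
  for (w in labels$positive_labels) {
    s_pos <- s_pos + ref_cosine(v, table$vectors[w, ])
  }
  s_neg <- 0
  for (w in labels$negative_labels) {
    s_neg <- s_neg + ref_cosine(v, table$vectors[w, ])
  }
  s_pos / length(labels$positive_labels) -
    s_neg / length(labels$negative_labels)
}

# Per-sentence reference scoring: plain loops over words and labels.
ref_score_sentence <- function(tokens, labels, table) {
  content <- tokens[tokens$pos_class %in% c("NOUN", "VERB", "ADJ", "ADV"), ]
  aaps <- c()
  pos_classes <- c()
  emotions <- matrix(numeric(0), ncol = 6)
  emo_names <- c("anger", "disgust", "fear", "happiness", "sadness",
                 "surprise")
  n_scored <- 0L
  if (nrow(content) > 0L) {
    for (i in seq_len(nrow(content))) {
      v <- ref_lookup(content$surface[[i]], content$lemma[[i]], table)
      if (is.null(v)) next
      n_scored <- n_scored + 1L
      aaps <- c(aaps, ref_word_aap(v, labels, table))
      pos_classes <- c(pos_classes, content$pos_class[[i]])
      e <- vapply(emo_names, function(nm) {
        ref_cosine(v, table$vectors[labels$emotion_labels[[nm]], ])
      }, numeric(1))
      emotions <- rbind(emotions, e)
    }
  }
  by_pos <- vapply(c("NOUN", "VERB", "ADJ", "ADV"), function(cls) {
    sel <- pos_classes == cls
    if (n_scored == 0L || !any(sel)) NA_real_ else mean(aaps[sel])
  }, numeric(1))
  list(
    n_scored = n_scored,
    aap = if (n_scored > 0L) mean(aaps) else NA_real_,
    by_pos = by_pos,
    emotions = if (n_scored > 0L) colMeans(emotions) else
      rep(NA_real_, 6L),
    n_positive = if (n_scored > 0L) sum(aaps > 0) else 0L,
    n_negative = if (n_scored > 0L) sum(aaps < 0) else 0L
  )
}
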