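# Internal helpers shared across modules.

# Classed conditions so callers (and the pipeline driver) can distinguish
# parse errors, configuration errors and scoring errors.
abort_sb <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "sentibook_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 1
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# POS classes whose tokens count as content words.
CONTENT_POS <- c("NOUN", "VERB", "ADJ", "ADV")

EMOTION_NAMES <- c("anger", "disgust", "fear", "happiness", "sadness", "surprise")

# The 18 book-profile features, in stable output order.
PROFILE_FEATURES <- c(
  "n_sentences", "words_per_sentence", "tokens", "types", "word_length", "ttr",
  "aap", "aap_noun", "aap_verb", "aap_adjective", "aap_adverb",
  EMOTION_NAMES, "pnr"
)

# Affect features aggregated over sentences (carry sd/sem companions).
AFFECT_FEATURES <- c(
  "aap", "aap_noun", "aap_verb", "aap_adjective", "aap_adverb",
  EMOTION_NAMES, "pnr"
)
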