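# Corpus ingestion: sentence segmentation, tokenization + POS tagging behind
# a pluggable tagger contract, content-word filtering, and lexical statistics.

# Abbreviations whose trailing period must not end a sentence.
ABBREVIATIONS <- c(
  "Mr", "Mrs", "Ms", "Dr", "Prof", "St", "Jr", "Sr", "Rev", "Hon", "Capt",
  "Col", "Gen", "Lt", "Sgt", "vs", "etc", "e.g", "i.e", "cf", "No", "Vol"
)

#' Split raw book text into sentences
#'
#' Punctuation-driven segmentation: sentences end at `.`, `!` or `?`
#' followed by whitespace, with a guard list of common abbreviations
#' (Mr., Dr., etc.) whose periods never terminate a sentence. The
#' concatenation of the returned sentences covers the text modulo the
#' delimiting whitespace.
#'
#' @param text Raw book text (single string); must be non-empty after
#'   whitespace stripping.
#' @return Character vector of sentence strings, in order.
#' @examples
#' segment_sentences("The cat sat. The dog ran.")
#' segment_sentences("Mr. Smith left.")
#' @export
segment_sentences <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    abort_sb("`text` must be a single string", "sentibook_config_error")
  }
  text <- trimws(gsub("[ \t\r\n]+", " ", text))
  if (!nzchar(text)) {
    abort_sb("empty book: no text after whitespace stripping",
             "sentibook_empty_error")
  }
  guard <- "․"  # ONE DOT LEADER stands in for protected periods
  for (ab in ABBREVIATIONS) {
    protected <- gsub(".", guard, ab, fixed = TRUE)
    text <- gsub(paste0("\\b", gsub("\\.", "\\\\.", ab), "\\."),
                 paste0(protected, guard), text, perl = TRUE)
  }
  pieces <- strsplit(text, "(?<=[.!?])[\"')”]?\\s+", perl = TRUE)[[1L]]
  pieces <- gsub(guard, ".", pieces, fixed = TRUE)
  pieces <- pieces[nzchar(trimws(pieces))]
  trimws(pieces)
}

word_token_pattern <- "\\p{L}+(?:-\\p{L}+)*"
token_pattern <- paste0(word_token_pattern, "|\\p{N}+|[^\\p{L}\\p{N}\\s]+")

# Split a sentence into tokens: maximal alphabetic runs (internal hyphens
# allowed), numeral runs, and punctuation clusters.
tokenize_sentence <- function(sentence) {
  m <- gregexpr(token_pattern, sentence, perl = TRUE)
  regmatches(sentence, m)[[1L]]
}

is_word_token <- function(tokens) grepl("\\p{L}", tokens, perl = TRUE)

#' Build a deterministic lexicon-based tagger
#'
#' The tagger contract: a function that, given a character vector of word
#' tokens, returns a data frame with columns `lemma` and `pos_class` (one of
#' NOUN, VERB, ADJ, ADV, OTHER), deterministically. This bundled
#' implementation looks each token up in a fixed lexicon (exact surface
#' first, then case-folded) and defaults to OTHER with the surface as lemma.
#'
#' @param lexicon Data frame with columns `surface`, `lemma`, `pos_class`.
#' @return A tagger function usable with [tokenize_and_tag()].
#' @seealso [read_tagger_lexicon()]
#' @export
lexicon_tagger <- function(lexicon) {
  lexicon <- as.data.frame(lexicon, stringsAsFactors = FALSE)
  need <- c("surface", "lemma", "pos_class")
  if (!all(need %in% names(lexicon))) {
    abort_sb("lexicon needs columns surface, lemma, pos_class",
             "sentibook_config_error")
  }
  bad_pos <- setdiff(unique(lexicon$pos_class), c(CONTENT_POS, "OTHER"))
  if (length(bad_pos) > 0L) {
    abort_sb(sprintf("unknown pos_class in lexicon: %s",
                     paste(bad_pos, collapse = ", ")),
             "sentibook_config_error")
  }
  lexicon <- lexicon[!duplicated(lexicon$surface), , drop = FALSE]
  env <- new.env(parent = emptyenv(), size = max(1L, nrow(lexicon)))
  for (i in seq_len(nrow(lexicon))) {
    assign(lexicon$surface[[i]],
           c(lexicon$lemma[[i]], lexicon$pos_class[[i]]), envir = env)
  }
  function(words) {
    out <- lapply(words, function(w) {
      hit <- get0(w, envir = env, inherits = FALSE)
      if (is.null(hit)) hit <- get0(tolower(w), envir = env, inherits = FALSE)
      if (is.null(hit)) c(w, "OTHER") else hit
    })
    data.frame(
      lemma = vapply(out, `[[`, character(1), 1L),
      pos_class = vapply(out, `[[`, character(1), 2L),
      stringsAsFactors = FALSE
    )
  }
}

#' Read a tagger lexicon from TSV
#'
#' @param path TSV file with columns `surface`, `lemma`, `pos_class`.
#' @return A data frame suitable for [lexicon_tagger()].
#' @export
read_tagger_lexicon <- function(path) {
  if (!file.exists(path)) {
    abort_sb(sprintf("tagger lexicon not found: %s", path),
             "sentibook_config_error")
  }
  read.delim(path, stringsAsFactors = FALSE, quote = "",
             fileEncoding = "UTF-8")
}

#' Tokenize a sentence and POS-tag its tokens
#'
#' Word tokens are passed to the tagger; punctuation and numeral tokens map
#' to OTHER unconditionally. Token order is preserved.
#'
#' @param sentence A sentence string.
#' @param tagger A tagger function (see [lexicon_tagger()] for the contract).
#' @param sentence_index Optional index carried into error messages.
#' @return A tibble of tagged tokens with columns `surface`, `lemma`,
#'   `pos_class`.
#' @export
tokenize_and_tag <- function(sentence, tagger, sentence_index = NA_integer_) {
  toks <- tokenize_sentence(sentence)
  if (length(toks) == 0L) {
    return(tibble::tibble(surface = character(), lemma = character(),
                          pos_class = character()))
  }
  wordlike <- is_word_token(toks)
  lemma <- toks
  pos <- rep("OTHER", length(toks))
  if (any(wordlike)) {
    tagged <- tryCatch(
      tagger(toks[wordlike]),
      error = function(e) {
        abort_sb(
          sprintf("tagger failed on sentence %s: %s",
                  ifelse(is.na(sentence_index), "?", sentence_index),
                  conditionMessage(e)),
          "sentibook_tagging_error"
        )
      }
    )
    if (!is.data.frame(tagged) ||
        !all(c("lemma", "pos_class") %in% names(tagged)) ||
        nrow(tagged) != sum(wordlike)) {
      abort_sb(
        sprintf("tagger broke its contract on sentence %s",
                ifelse(is.na(sentence_index), "?", sentence_index)),
        "sentibook_tagging_error"
      )
    }
    lemma[wordlike] <- tagged$lemma
    pos[wordlike] <- tagged$pos_class
  }
  tibble::tibble(surface = toks, lemma = lemma, pos_class = pos)
}

#' Keep only content words
#'
#' Filters a tagged-token table to the tokens whose `pos_class` is NOUN,
#' VERB, ADJ or ADV, preserving order. Idempotent.
#'
#' @param tokens Tibble from [tokenize_and_tag()].
#' @return The content-word subset, same columns.
#' @export
filter_content_words <- function(tokens) {
  tokens[tokens$pos_class %in% CONTENT_POS, , drop = FALSE]
}

#' Build a book document from raw text
#'
#' Segments the text into sentences, tags each one, and wraps the result in
#' the per-book container consumed by scoring. Sentence indices are 0-based
#' and consecutive.
#'
#' @param text Raw book text.
#' @param tagger Tagger function (see [lexicon_tagger()]).
#' @param book_id Identifier string.
#' @param title,author Optional metadata strings.
#' @return An object of class `book_document`: `book_id`, `title`, `author`,
#'   and `sentences`, a list of records with fields `index` (0-based) and
#'   `tokens` (tibble of tagged tokens).
#' @export
book_document <- function(text, tagger, book_id = "book",
                          title = "", author = "") {
  sents <- segment_sentences(text)
  records <- lapply(seq_along(sents), function(i) {
    list(index = i - 1L,
         tokens = tokenize_and_tag(sents[[i]], tagger, sentence_index = i - 1L))
  })
  structure(
    list(book_id = book_id, title = title, author = author,
         sentences = records),
    class = "book_document"
  )
}

#' @export
print.book_document <- function(x, ...) {
  cat(sprintf("<book_document> %s: %d sentences\n",
              x$book_id, length(x$sentences)))
  invisible(x)
}

#' Read a corpus from a manifest
#'
#' The manifest is a TSV with columns `book_id`, `path` (UTF-8 plain-text
#' file per book, relative paths resolved against the manifest's directory)
#' and optional `title`, `author`.
#'
#' @param manifest_path Path to the manifest TSV.
#' @param tagger Tagger function applied to every book.
#' @return A list of [book_document()] objects.
#' @export
read_corpus <- function(manifest_path, tagger) {
  if (!file.exists(manifest_path)) {
    abort_sb(sprintf("corpus manifest not found: %s", manifest_path),
             "sentibook_config_error")
  }
  man <- read.delim(manifest_path, stringsAsFactors = FALSE, quote = "",
                    fileEncoding = "UTF-8")
  if (!all(c("book_id", "path") %in% names(man)) || nrow(man) == 0L) {
    abort_sb("manifest needs columns book_id and path, with at least one row",
             "sentibook_config_error")
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[[i]]
    if (!file.exists(p)) p <- file.path(base, man$path[[i]])
    if (!file.exists(p)) {
      abort_sb(sprintf("book file not found: %s", man$path[[i]]),
               "sentibook_config_error")
    }
    txt <- paste(readLines(p, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n")
    book_document(
      txt, tagger, book_id = man$book_id[[i]],
      title = if ("title" %in% names(man)) man$title[[i]] else "",
      author = if ("author" %in% names(man)) man$author[[i]] else ""
    )
  })
}

#' Lexical statistics of a book
#'
#' Tokens are all word tokens (punctuation and numerals excluded); types are
#' distinct case-folded tokens; word length is the mean number of letters
#' per token; the type-token ratio is types/tokens.
#'
#' @param book A [book_document()].
#' @return A one-row tibble: `n_sentences`, `mean_words_per_sentence`,
#'   `n_tokens`, `n_types`, `mean_word_length`, `type_token_ratio`.
#' @export
compute_corpus_stats <- function(book) {
  stopifnot(inherits(book, "book_document"))
  if (length(book$sentences) == 0L) {
    abort_sb("book has no sentences", "sentibook_empty_error")
  }
  words <- unlist(lapply(book$sentences, function(s) {
    s$tokens$surface[is_word_token(s$tokens$surface)]
  }))
  n_tokens <- length(words)
  n_types <- length(unique(tolower(words)))
  letters_per_word <- nchar(gsub("[^\\p{L}]", "", words, perl = TRUE))
  tibble::tibble(
    n_sentences = length(book$sentences),
    mean_words_per_sentence = n_tokens / length(book$sentences),
    n_tokens = n_tokens,
    n_types = n_types,
    mean_word_length = if (n_tokens > 0L) mean(letters_per_word) else NA_real_,
    type_token_ratio = if (n_tokens > 0L) n_types / n_tokens else NA_real_
  )
}

#' Embedding coverage (hit-rate) of a corpus
#'
#' The fraction of content-word tokens (not types) across all books for
#' which [vector_lookup()] succeeds, using the lemma as fallback form.
#'
#' @param books List of [book_document()] objects (a single book is
#'   accepted).
#' @param table A [word_vector_table()].
#' @return A number in `[0, 1]`.
#' @export
compute_hit_rate <- function(books, table) {
  if (inherits(books, "book_document")) books <- list(books)
  n_content <- 0L
  n_hit <- 0L
  for (book in books) {
    for (s in book$sentences) {
      ct <- filter_content_words(s$tokens)
      n_content <- n_content + nrow(ct)
      if (nrow(ct) > 0L) {
        hits <- mapply(function(w, l) {
          !is.null(vector_lookup(w, table, fallback_form = l))
        }, ct$surface, ct$lemma)
        n_hit <- n_hit + sum(hits)
      }
    }
  }
  if (n_content == 0L) {
    abort_sb("coverage undefined: no content tokens in corpus",
             "sentibook_empty_error")
  }
  n_hit / n_content
}
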