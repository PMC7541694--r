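# Vector space model: word-vector table, cosine similarity, lookup rules,
# and the affect-label configuration.

#' Construct a word-vector table
#'
#' Wraps a numeric matrix of word embeddings (one row per word, rownames are
#' the vocabulary) into the container used by all scoring functions. Vectors
#' are stored exactly as supplied; unit-normalization happens inside
#' [cosine_similarity()], so the table round-trips through its file format.
#'
#' @param vectors Numeric matrix, one row per word; rownames give the
#'   vocabulary. No row may be all-zero and rownames must be unique.
#' @param case_policy Metadata string recording how the vocabulary is cased
#'   (`"as-is"` by default); lookups case-fold as a fallback regardless.
#' @return An object of class `word_vector_table` with elements `vocabulary`,
#'   `dimension`, `vectors` and `metadata`.
#' @seealso [read_word_vectors()], [vector_lookup()]
#' @export
word_vector_table <- function(vectors, case_policy = "as-is") {
  if (!is.matrix(vectors) || !is.numeric(vectors)) {
    abort_sb("`vectors` must be a numeric matrix", "sentibook_config_error")
  }
  vocab <- rownames(vectors)
  if (is.null(vocab) || anyNA(vocab) || any(!nzchar(vocab))) {
    abort_sb("`vectors` must have non-empty rownames (the vocabulary)",
             "sentibook_config_error")
  }
  if (anyDuplicated(vocab)) {
    abort_sb("vocabulary entries must be unique", "sentibook_config_error")
  }
  if (ncol(vectors) < 1L) {
    abort_sb("embedding dimension must be at least 1", "sentibook_config_error")
  }
  zero <- rowSums(vectors != 0) == 0L
  if (any(zero)) {
    abort_sb(
      sprintf("all-zero vector(s) in table: %s",
              paste(head(vocab[zero], 5L), collapse = ", ")),
      "sentibook_config_error"
    )
  }
  index <- new.env(parent = emptyenv(), size = nrow(vectors))
  for (i in seq_along(vocab)) assign(vocab[[i]], i, envir = index)
  structure(
    list(
      vocabulary = vocab,
      dimension = ncol(vectors),
      vectors = vectors,
      index = index,
      metadata = list(case_policy = case_policy)
    ),
    class = "word_vector_table"
  )
}

#' @export
print.word_vector_table <- function(x, ...) {
  cat(sprintf("<word_vector_table> %d words, dimension %d\n",
              length(x$vocabulary), x$dimension))
  invisible(x)
}

#' Read word vectors in word2vec/fastText text format
#'
#' Parses a UTF-8, space-separated `.vec`/`.txt` embedding file: an optional
#' one-line `"count dim"` header (detected automatically) followed by one
#' `word v1 ... vd` line per word. Duplicate words keep their first
#' occurrence with a warning.
#'
#' @param path Path to the embedding file.
#' @param expected_dimension Optional integer; a mismatch with the file's
#'   dimension raises a configuration error.
#' @return A [word_vector_table()].
#' @examples
#' f <- tempfile(fileext = ".vec")
#' writeLines(c("3 2", "cat 1 0", "dog 0 1", "sun 1 1"), f)
#' tab <- read_word_vectors(f)
#' tab$dimension
#' @export
read_word_vectors <- function(path, expected_dimension = NULL) {
  if (!file.exists(path)) {
    abort_sb(sprintf("embedding file not found: %s", path),
             "sentibook_config_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort_sb("embedding file is empty", "sentibook_parse_error")
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  first_line_no <- 1L
  header <- NULL
  f1 <- fields[[1L]]
  if (length(f1) == 2L && !anyNA(suppressWarnings(as.numeric(f1)))) {
    header <- as.numeric(f1)
    fields <- fields[-1L]
    first_line_no <- 2L
    if (length(fields) == 0L) {
      abort_sb("embedding file has a header but no vectors",
               "sentibook_parse_error")
    }
  }
  dim_file <- length(fields[[1L]]) - 1L
  if (!is.null(header) && header[[2L]] != dim_file) {
    dim_file <- as.integer(header[[2L]])  # trust header; lines checked below
  }
  if (dim_file < 1L) {
    abort_sb(sprintf("line %d: no vector components", first_line_no),
             "sentibook_parse_error")
  }
  nfield <- lengths(fields)
  bad <- which(nfield != dim_file + 1L)
  if (length(bad) > 0L) {
    abort_sb(
      sprintf("line %d: expected %d fields (word + %d values), found %d",
              bad[[1L]] + first_line_no - 1L, dim_file + 1L, dim_file,
              nfield[[bad[[1L]]]]),
      "sentibook_parse_error"
    )
  }
  words <- vapply(fields, `[[`, character(1), 1L)
  values <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-1L]), numeric(dim_file))
  )
  values <- matrix(values, ncol = dim_file, byrow = TRUE)
  na_row <- which(apply(is.na(values), 1L, any))
  if (length(na_row) > 0L) {
    abort_sb(
      sprintf("line %d: non-numeric vector component",
              na_row[[1L]] + first_line_no - 1L),
      "sentibook_parse_error"
    )
  }
  if (!is.null(expected_dimension) && dim_file != expected_dimension) {
    abort_sb(
      sprintf("embedding dimension %d does not match expected %d",
              dim_file, as.integer(expected_dimension)),
      "sentibook_config_error"
    )
  }
  dup <- duplicated(words)
  if (any(dup)) {
    warning(sprintf("dropping %d duplicate vocabulary entr%s (first kept): %s",
                    sum(dup), if (sum(dup) == 1L) "y" else "ies",
                    paste(unique(head(words[dup], 5L)), collapse = ", ")),
            call. = FALSE)
    words <- words[!dup]
    values <- values[!dup, , drop = FALSE]
  }
  rownames(values) <- words
  word_vector_table(values)
}

#' Cosine similarity between two vectors
#'
#' The standard cosine, symmetric in its arguments and invariant under
#' positive rescaling of either one. The result is clamped to `[-1, 1]`
#' against floating-point rounding. Zero vectors have no direction, so the
#' similarity is undefined and an error is raised (never a silent 0).
#'
#' @param a,b Numeric vectors of equal length, neither all-zero.
#' @return A number in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(3, 4), c(4, 3))  # 24/25 = 0.96
#' @export
cosine_similarity <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b)) {
    abort_sb("`a` and `b` must be numeric vectors of equal length",
             "sentibook_config_error")
  }
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    abort_sb("cosine similarity is undefined for a zero vector",
             "sentibook_zero_vector_error")
  }
  max(-1, min(1, sum(a * b) / (na * nb)))
}

#' Look up a token's vector with deterministic fallbacks
#'
#' Tries the exact surface form, then the case-folded (lower-cased) form,
#' then `fallback_form` (intended for a tagger-supplied lemma, itself tried
#' exact then case-folded). A miss is a normal value (`NULL`), not an error;
#' coverage accounting counts it.
#'
#' @param token Non-empty word string.
#' @param table A [word_vector_table()].
#' @param fallback_form Optional word string tried after the surface forms.
#' @return The word's numeric vector, or `NULL` if not found.
#' @export
vector_lookup <- function(token, table, fallback_form = NULL) {
  stopifnot(inherits(table, "word_vector_table"))
  if (!is.character(token) || length(token) != 1L || !nzchar(token)) {
    abort_sb("`token` must be a single non-empty string",
             "sentibook_config_error")
  }
  candidates <- c(token, tolower(token))
  if (!is.null(fallback_form) && !is.na(fallback_form) && nzchar(fallback_form)) {
    candidates <- c(candidates, fallback_form, tolower(fallback_form))
  }
  for (cand in unique(candidates)) {
    i <- get0(cand, envir = table$index, inherits = FALSE)
    if (!is.null(i)) return(table$vectors[i, ])
  }
  NULL
}

#' Construct an affect-label configuration
#'
#' Holds the positive and negative label sets that define the
#' affective-aesthetic potential (AAP: mean cosine to positive labels minus
#' mean cosine to negative labels) and the six single-word discrete-emotion
#' labels. The positive and negative sets must be non-empty and disjoint;
#' exactly the six emotions anger, disgust, fear, happiness, sadness and
#' surprise must be labelled.
#'
#' @param positive_labels,negative_labels Character vectors of label words.
#' @param emotion_labels Named character vector or list mapping each of the
#'   six emotion names to a single label word.
#' @return An object of class `label_config`.
#' @export
label_config <- function(positive_labels, negative_labels, emotion_labels) {
  positive_labels <- as.character(positive_labels)
  negative_labels <- as.character(negative_labels)
  if (length(positive_labels) == 0L || length(negative_labels) == 0L) {
    abort_sb("positive and negative label sets must be non-empty",
             "sentibook_config_error")
  }
  overlap <- intersect(positive_labels, negative_labels)
  if (length(overlap) > 0L) {
    abort_sb(
      sprintf("positive and negative label sets overlap: %s",
              paste(head(overlap, 5L), collapse = ", ")),
      "sentibook_config_error"
    )
  }
  emotion_labels <- unlist(emotion_labels)
  if (!setequal(names(emotion_labels), EMOTION_NAMES) ||
      length(emotion_labels) != 6L) {
    abort_sb(
      sprintf("emotion labels must name exactly: %s",
              paste(EMOTION_NAMES, collapse = ", ")),
      "sentibook_config_error"
    )
  }
  structure(
    list(
      positive_labels = unique(positive_labels),
      negative_labels = unique(negative_labels),
      emotion_labels = emotion_labels[EMOTION_NAMES]
    ),
    class = "label_config"
  )
}

#' @export
print.label_config <- function(x, ...) {
  cat(sprintf("<label_config> %d positive, %d negative, 6 emotion labels\n",
              length(x$positive_labels), length(x$negative_labels)))
  invisible(x)
}

#' Read a label configuration from JSON or YAML
#'
#' The file must contain keys `positive_labels`, `negative_labels` and
#' `emotion_labels` (the latter a map from the six emotion names to single
#' words). Format is chosen by extension: `.json` via jsonlite, anything
#' else via yaml.
#'
#' @param path Path to the configuration file.
#' @return A [label_config()].
#' @export
read_label_config <- function(path) {
  if (!file.exists(path)) {
    abort_sb(sprintf("label config not found: %s", path),
             "sentibook_config_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (key in c("positive_labels", "negative_labels", "emotion_labels")) {
    if (is.null(raw[[key]])) {
      abort_sb(sprintf("label config is missing key '%s'", key),
               "sentibook_config_error")
    }
  }
  label_config(raw$positive_labels, raw$negative_labels, raw$emotion_labels)
}

#' Validate labels against a vector table
#'
#' Checks that every AAP and emotion label resolves in the table (via
#' [vector_lookup()]). The report carries the failures; it is the caller's
#' contract (enforced by [run_pipeline()]) that scoring refuses to start
#' while `ok` is `FALSE`.
#'
#' @param labels A [label_config()].
#' @param table A [word_vector_table()].
#' @return A list with `ok` (logical) and `missing` (character vector of
#'   unresolvable labels).
#' @export
validate_labels <- function(labels, table) {
  stopifnot(inherits(labels, "label_config"))
  all_labels <- c(labels$positive_labels, labels$negative_labels,
                  unname(labels$emotion_labels))
  missing <- all_labels[vapply(
    all_labels, function(w) is.null(vector_lookup(w, table)), logical(1)
  )]
  list(ok = length(missing) == 0L, missing = unique(missing))
}

# Unit-normalized label matrices, precomputed once per (labels, table) pair;
# scoring then reduces to matrix-vector products.
label_matrices <- function(labels, table) {
  check <- validate_labels(labels, table)
  if (!check$ok) {
    abort_sb(
      sprintf("labels not in vector table: %s",
              paste(check$missing, collapse = ", ")),
      "sentibook_label_error"
    )
  }
  fetch <- function(words) {
    m <- matrix(
      unlist(lapply(words, function(w) vector_lookup(w, table))),
      ncol = table$dimension, byrow = TRUE
    )
    rownames(m) <- words
    m / sqrt(rowSums(m * m))
  }
  list(
    positive = fetch(labels$positive_labels),
    negative = fetch(labels$negative_labels),
    emotion = fetch(unname(labels$emotion_labels))
  )
}
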