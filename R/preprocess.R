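# Text normalisation and embedding lookup: lowercase, strip punctuation,
# drop stopwords, stem (injected contract, identity by default), and the
# GloVe text-format reader. The post-preprocessing token count defines the
# note length L used downstream.

#' Read and write note corpora (JSONL)
#'
#' One JSON object per line with fields `id`, `stage` (one of `I`, `II`,
#' `palliative`), `text`, and an optional `expert_flags` object with entries
#' `body_image`, `self_esteem` (codes -1/0/1/2), `pain` (0/1) and `sentiment`
#' (-1/0/1). Flags are surfaced as `flag_*` columns (`NA` when absent).
#'
#' @param path file path to the JSONL corpus.
#' @return a tibble with columns `id`, `stage`, `text`, `flag_body_image`,
#'   `flag_self_esteem`, `flag_pain`, `flag_sentiment`.
#' @export
read_notes <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  get_flag <- function(r, name) {
    f <- r$expert_flags[[name]]
    if (is.null(f)) NA_integer_ else as.integer(f)
  }
  out <- tibble::tibble(
    id = vapply(recs, function(r) as.character(r$id), character(1)),
    stage = vapply(recs, function(r) as.character(r$stage), character(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1)),
    flag_body_image = vapply(recs, get_flag, integer(1), "body_image"),
    flag_self_esteem = vapply(recs, get_flag, integer(1), "self_esteem"),
    flag_pain = vapply(recs, get_flag, integer(1), "pain"),
    flag_sentiment = vapply(recs, get_flag, integer(1), "sentiment")
  )
  if (anyDuplicated(out$id)) {
    abort("Note ids must be unique within a corpus.",
          class = "onconotes_validation_error")
  }
  bad <- setdiff(unique(out$stage), stage_levels())
  if (length(bad) > 0) {
    abort(paste0("Unknown stage label(s): ", paste(bad, collapse = ", ")),
          class = "onconotes_validation_error")
  }
  check_range <- function(v, ok, what) {
    if (!all(v %in% c(ok, NA))) {
      abort(paste0("Expert flag `", what, "` outside its allowed codes."),
            class = "onconotes_validation_error")
    }
  }
  check_range(out$flag_body_image, c(-1L, 0L, 1L, 2L), "body_image")
  check_range(out$flag_self_esteem, c(-1L, 0L, 1L, 2L), "self_esteem")
  check_range(out$flag_pain, c(0L, 1L), "pain")
  check_range(out$flag_sentiment, c(-1L, 0L, 1L), "sentiment")
  out
}

#' @rdname read_notes
#' @param notes a notes tibble.
#' @export
write_notes <- function(notes, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    flags <- list()
    if (!is.na(notes$flag_body_image[i])) flags$body_image <- notes$flag_body_image[i]
    if (!is.na(notes$flag_self_esteem[i])) flags$self_esteem <- notes$flag_self_esteem[i]
    if (!is.na(notes$flag_pain[i])) flags$pain <- notes$flag_pain[i]
    if (!is.na(notes$flag_sentiment[i])) flags$sentiment <- notes$flag_sentiment[i]
    rec <- list(id = notes$id[i], stage = notes$stage[i], text = notes$text[i])
    if (length(flags) > 0) rec$expert_flags <- flags
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Preprocess notes into token streams
#'
#' Normalises each note's raw text: lowercase, punctuation stripped, split on
#' whitespace, stopwords removed, each remaining token stemmed. The resulting
#' stem sequence (order preserved) is stored in a `tokens` list-column and
#' its length in `n_tokens`; this post-preprocessing count is the note
#' length used by the emotion and saturation statistics. The raw `text` is
#' left untouched, and preprocessing is idempotent on already-clean token
#' streams.
#'
#' @param notes a notes tibble (see [read_notes()]); `text` must be non-empty.
#' @param stopwords character vector of stopwords (matched after lowercasing,
#'   before stemming).
#' @param stemmer optional function word -> stem (default: identity).
#' @return `notes` with `tokens` and `n_tokens` columns added. Notes whose
#'   text consists solely of stopwords are retained with an empty token list.
#' @export
preprocess_notes <- function(notes, stopwords = character(), stemmer = NULL) {
  if (!all(c("id", "text") %in% names(notes))) {
    abort("`notes` must have `id` and `text` columns.",
          class = "onconotes_input_error")
  }
  empty <- !nzchar(trimws(notes$text))
  if (any(empty)) {
    abort(paste0("Empty or whitespace-only text in note(s): ",
                 paste(head(notes$id[empty], 5), collapse = ", ")),
          class = "onconotes_empty_note_error")
  }
  stopwords <- stringr::str_to_lower(stopwords)
  clean <- stringr::str_to_lower(notes$text)
  # strip (not split on) punctuation so the token count never exceeds the
  # raw whitespace token count
  clean <- stringr::str_remove_all(clean, "[^\\p{L}\\p{N}_\\s]")
  toks <- stringr::str_split(clean, "\\s+")
  notes$tokens <- lapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    tk <- tk[!tk %in% stopwords]
    apply_stemmer(tk, stemmer)
  })
  notes$n_tokens <- lengths(notes$tokens)
  if (any(notes$n_tokens == 0)) {
    inform(paste0(sum(notes$n_tokens == 0),
                  " note(s) empty after stopword removal; retained."))
  }
  tibble::as_tibble(notes)
}

#' Read and write word vectors (GloVe text format)
#'
#' One line per word: the word followed by its vector components, separated
#' by whitespace. Malformed lines (wrong component count or non-numeric
#' values) are skipped with a warning, or raise an error when `strict = TRUE`.
#'
#' @param path file path.
#' @param expected_dim expected vector dimension; inferred from the first
#'   well-formed line when `NULL`. Required for empty files.
#' @param strict raise an error on malformed lines instead of skipping.
#' @return a numeric matrix with words as rownames, one row per word.
#' @export
read_embeddings <- function(path, expected_dim = NULL, strict = FALSE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    if (is.null(expected_dim)) {
      abort("Empty vector file and no `expected_dim` supplied.",
            class = "onconotes_format_error")
    }
    return(matrix(numeric(0), nrow = 0, ncol = expected_dim,
                  dimnames = list(character(0), NULL)))
  }
  parts <- strsplit(lines, "[ \t]+")
  dim_here <- expected_dim
  words <- character(0)
  rows <- list()
  bad_lines <- integer(0)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    vals <- suppressWarnings(as.numeric(p[-1]))
    ok <- length(p) >= 2 && !anyNA(vals)
    if (ok && is.null(dim_here)) dim_here <- length(vals)
    ok <- ok && length(vals) == dim_here
    if (!ok) {
      if (strict) {
        abort(paste0("Malformed vector line ", i, " in ", path),
              class = "onconotes_format_error")
      }
      bad_lines <- c(bad_lines, i)
      next
    }
    words <- c(words, p[1])
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(bad_lines) > 0) {
    warn(paste0("Skipped ", length(bad_lines), " malformed vector line(s) ",
                "in ", path, " (first: line ", bad_lines[1], ")."))
  }
  mat <- do.call(rbind, rows)
  if (is.null(mat)) {
    mat <- matrix(numeric(0), nrow = 0, ncol = dim_here %||% 0)
  }
  if (anyDuplicated(words)) {
    warn("Duplicate words in vector file; last occurrence retained.")
    keep <- !duplicated(words, fromLast = TRUE)
    mat <- mat[keep, , drop = FALSE]
    words <- words[keep]
  }
  rownames(mat) <- words
  mat
}

#' @rdname read_embeddings
#' @param embeddings a numeric matrix with words as rownames.
#' @export
write_embeddings <- function(embeddings, path) {
  assert_embeddings(embeddings)
  lines <- vapply(seq_len(nrow(embeddings)), function(i) {
    paste(rownames(embeddings)[i],
          paste(sprintf("%.10g", embeddings[i, ]), collapse = " "))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Look up embeddings for a token sequence
#'
#' Maps each in-vocabulary token to its vector. Out-of-vocabulary tokens are
#' either dropped (`oov = "skip"`, the default — expansion and modelling only
#' consider words with embeddings) or replaced by a zero vector
#' (`oov = "zero"`).
#'
#' @param tokens character vector of stems.
#' @param embeddings embedding matrix (words as rownames).
#' @param oov out-of-vocabulary policy.
#' @return a numeric matrix, one row per retained token (rownames = tokens,
#'   order preserved).
#' @export
embed_tokens <- function(tokens, embeddings, oov = c("skip", "zero")) {
  oov <- match.arg(oov)
  assert_embeddings(embeddings)
  idx <- match(tokens, rownames(embeddings))
  if (oov == "skip") {
    keep <- !is.na(idx)
    out <- embeddings[idx[keep], , drop = FALSE]
    rownames(out) <- tokens[keep]
  } else {
    out <- matrix(0, nrow = length(tokens), ncol = ncol(embeddings))
    hit <- !is.na(idx)
    out[hit, ] <- embeddings[idx[hit], , drop = FALSE]
    rownames(out) <- tokens
  }
  out
}
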