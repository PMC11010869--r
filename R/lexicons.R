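# Lexicon data model and I/O: affective lexicon (word -> polarity + five
# emotion intensities), polarity lexicon (word -> polarity), and per-topic
# dictionaries (positive/negative word lists; pain has a single list).
# Words are lowercased and stemmed at load time so all downstream matching
# operates on stems.

apply_stemmer <- function(words, stemmer = NULL) {
  words <- stringr::str_to_lower(words)
  if (!is.null(stemmer)) {
    words <- vapply(words, function(w) as.character(stemmer(w)), character(1),
                    USE.NAMES = FALSE)
  }
  words
}

#' Dominant emotion of affective entries
#'
#' Returns, for each row of a table carrying the five emotion-intensity
#' columns, the label of the maximal intensity. Ties are broken by the fixed
#' canonical order `happiness, sadness, anger, disgust, fear`; rows whose
#' intensities are all zero yield the sentinel `"none"`.
#'
#' @param intensities a data frame (or affective lexicon tibble) containing
#'   numeric columns named after [emotion_labels()].
#' @return character vector, one label (or `"none"`) per row.
#' @examples
#' dominant_emotion(tibble::tibble(
#'   happiness = c(0.1, 0.5, 0), sadness = c(0.9, 0.5, 0),
#'   anger = 0, disgust = 0, fear = 0
#' ))
#' @export
dominant_emotion <- function(intensities) {
  labs <- emotion_labels()
  miss <- setdiff(labs, names(intensities))
  if (length(miss) > 0) {
    abort(paste0("Missing intensity column(s): ", paste(miss, collapse = ", ")),
          class = "onconotes_input_error")
  }
  mat <- as.matrix(intensities[labs])
  if (nrow(mat) == 0) return(character(0))
  out <- labs[max.col(mat, ties.method = "first")]
  out[rowSums(mat) == 0] <- "none"
  out
}

validate_affective <- function(df, path = "<lexicon>") {
  labs <- emotion_labels()
  if (any(!nzchar(df$word))) {
    abort("Affective lexicon contains empty words.",
          class = "onconotes_validation_error")
  }
  if (!all(df$polarity %in% c(-1L, 0L, 1L))) {
    bad <- which(!df$polarity %in% c(-1L, 0L, 1L))
    abort(paste0("Polarity outside {-1, 0, 1} at row(s) ",
                 paste(head(bad, 5), collapse = ", "), " of ", path),
          class = "onconotes_validation_error")
  }
  for (e in labs) {
    v <- df[[e]]
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    if (length(bad) > 0) {
      abort(paste0("Intensity `", e, "` outside [0, 1] at row(s) ",
                   paste(head(bad, 5), collapse = ", "), " of ", path),
            class = "onconotes_validation_error")
    }
  }
  invisible(df)
}

#' Read and write an affective lexicon
#'
#' The affective lexicon maps each word to a polarity in \{-1, 0, +1\} and
#' intensities in \[0, 1\] for the five basic emotions. The on-disk format is
#' UTF-8 CSV with header `word,polarity,happiness,sadness,anger,disgust,fear`
#' and an optional `source` column (`seed` or `expanded`). On load, words are
#' lowercased and stemmed, intensities validated against \[0, 1\], and a
#' `dominant` column added (see [dominant_emotion()]).
#'
#' @param path file path to the CSV.
#' @param strict if `TRUE` (default), duplicate words are an error; otherwise
#'   the last occurrence wins and a message is emitted.
#' @param stemmer optional function word -> stem applied at load time
#'   (default: identity).
#' @return a tibble with columns `word`, `polarity`, the five emotions,
#'   `source`, and `dominant`.
#' @export
read_affective_lexicon <- function(path, strict = TRUE, stemmer = NULL) {
  req <- c("word", "polarity", emotion_labels())
  # parse numbers via base R strtod (correctly rounded) for bit-exact
  # round-trips
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    abort(paste0("Affective lexicon ", path, " is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "onconotes_format_error")
  }
  df$word <- apply_stemmer(as.character(df$word), stemmer)
  df$polarity <- as.integer(df$polarity)
  for (e in emotion_labels()) df[[e]] <- as.numeric(df[[e]])
  validate_affective(df, path)
  if (anyDuplicated(df$word)) {
    dups <- unique(df$word[duplicated(df$word)])
    if (strict) {
      abort(paste0("Duplicate word(s) in affective lexicon: ",
                   paste(head(dups, 5), collapse = ", ")),
            class = "onconotes_validation_error")
    }
    inform(paste0("Dropping earlier duplicates of ", length(dups),
                  " word(s); last occurrence retained."))
    df <- df[!duplicated(df$word, fromLast = TRUE), , drop = FALSE]
  }
  if (!"source" %in% names(df)) {
    df$source <- "seed"
  } else if (!all(df$source %in% c("seed", "expanded"))) {
    abort("`source` column must be 'seed' or 'expanded'.",
          class = "onconotes_validation_error")
  }
  out <- tibble::as_tibble(df[c(req, "source")])
  out$dominant <- dominant_emotion(out)
  out
}

#' @rdname read_affective_lexicon
#' @param lexicon an affective lexicon tibble.
#' @export
write_affective_lexicon <- function(lexicon, path) {
  cols <- c("word", "polarity", emotion_labels(), "source")
  out <- lexicon[intersect(cols, names(lexicon))]
  # 17 significant digits guarantee a bit-exact double round-trip
  for (e in emotion_labels()) out[[e]] <- sprintf("%.17g", out[[e]])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write a polarity lexicon
#'
#' A flat word list with polarity in \{-1, 0, +1\}, modelled on general
#' sentiment dictionaries. CSV format `word,polarity`; words are lowercased
#' and stemmed at load time.
#'
#' @inheritParams read_affective_lexicon
#' @return a tibble with columns `word` and `polarity`.
#' @export
read_polarity_lexicon <- function(path, strict = TRUE, stemmer = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("word", "polarity"), names(df))
  if (length(miss) > 0) {
    abort(paste0("Polarity lexicon ", path, " is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "onconotes_format_error")
  }
  df$word <- apply_stemmer(as.character(df$word), stemmer)
  df$polarity <- as.integer(df$polarity)
  if (any(!nzchar(df$word))) {
    abort("Polarity lexicon contains empty words.",
          class = "onconotes_validation_error")
  }
  if (!all(df$polarity %in% c(-1L, 0L, 1L))) {
    abort("Polarity values must be in {-1, 0, 1}.",
          class = "onconotes_validation_error")
  }
  if (anyDuplicated(df$word)) {
    if (strict) {
      abort("Duplicate word(s) in polarity lexicon.",
            class = "onconotes_validation_error")
    }
    inform("Duplicate words in polarity lexicon; last occurrence retained.")
    df <- df[!duplicated(df$word, fromLast = TRUE), , drop = FALSE]
  }
  tibble::as_tibble(df[c("word", "polarity")])
}

#' @rdname read_polarity_lexicon
#' @param lexicon a polarity lexicon tibble.
#' @export
write_polarity_lexicon <- function(lexicon, path) {
  readr::write_csv(lexicon[c("word", "polarity")], path, progress = FALSE)
  invisible(path)
}

#' Topic dictionaries for areas of difficulty
#'
#' A topic dictionary holds the positive and negative word lists for one
#' screened topic. The topics `body_image` and `self_esteem` require both
#' lists, non-empty and disjoint; the topic `pain` carries a single list
#' (its `negative` set must be empty) because pain is only detected as
#' present or absent. On-disk format is JSON:
#' `{"topic": "...", "positive": [...], "negative": [...]}`.
#'
#' @param topic one of `"body_image"`, `"self_esteem"`, `"pain"`.
#' @param positive,negative character vectors of terms (stems).
#' @param stemmer optional stemming function applied to all terms.
#' @return an object of class `topic_dictionary`.
#' @export
topic_dictionary <- function(topic, positive, negative = character(),
                             stemmer = NULL) {
  topics <- c("body_image", "self_esteem", "pain")
  if (!is.character(topic) || length(topic) != 1 || !topic %in% topics) {
    abort(paste0("`topic` must be one of: ", paste(topics, collapse = ", ")),
          class = "onconotes_validation_error")
  }
  positive <- unique(apply_stemmer(as.character(positive), stemmer))
  negative <- unique(apply_stemmer(as.character(negative), stemmer))
  if (topic == "pain") {
    if (length(negative) > 0) {
      abort("Pain dictionary must not carry a negative word list.",
            class = "onconotes_validation_error")
    }
    if (length(positive) == 0) {
      abort("Pain dictionary term list is empty.",
            class = "onconotes_validation_error")
    }
  } else {
    if (length(positive) == 0 || length(negative) == 0) {
      abort(paste0("Topic '", topic, "' requires non-empty positive and ",
                   "negative term lists."),
            class = "onconotes_validation_error")
    }
    both <- intersect(positive, negative)
    if (length(both) > 0) {
      abort(paste0("Term(s) in both positive and negative lists of '", topic,
                   "': ", paste(head(both, 5), collapse = ", ")),
            class = "onconotes_validation_error")
    }
  }
  structure(list(topic = topic, positive = positive, negative = negative),
            class = "topic_dictionary")
}

#' @rdname topic_dictionary
#' @param path file path to the JSON dictionary.
#' @export
read_topic_dictionary <- function(path, stemmer = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$topic)) {
    abort(paste0("Topic dictionary ", path, " lacks a 'topic' field."),
          class = "onconotes_format_error")
  }
  topic_dictionary(obj$topic,
                   positive = obj$positive %||% character(),
                   negative = obj$negative %||% character(),
                   stemmer = stemmer)
}

#' @rdname topic_dictionary
#' @param x a `topic_dictionary`.
#' @export
write_topic_dictionary <- function(x, path) {
  stopifnot(inherits(x, "topic_dictionary"))
  jsonlite::write_json(
    list(topic = x$topic, positive = x$positive, negative = x$negative),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @export
print.topic_dictionary <- function(x, ...) {
  cat("<topic_dictionary> ", x$topic, "\n",
      "  positive terms: ", length(x$positive), "\n",
      "  negative terms: ", length(x$negative), "\n", sep = "")
  invisible(x)
}

#' All terms of a topic dictionary
#'
#' Positive and negative lists concatenated (for pain, the single list).
#'
#' @param dict a [topic_dictionary()].
#' @return character vector of stems.
#' @export
topic_terms <- function(dict) {
  c(dict$positive, dict$negative)
}
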