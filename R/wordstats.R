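# Word-class frequency analysis: adjectives split by polarity, verbs by
# tense ("to be" vs others), possessive "my" in a body context, and the
# per-note adjective saturation percentages summarised by treatment stage.

#' Read and write a tag lexicon
#'
#' Deterministic stand-in for a part-of-speech tagger: a CSV
#' `word,pos,tense,is_to_be,is_my` mapping each word to a class
#' (`adjective`, `verb`, `other`), a tense for verbs (`past`, `present`,
#' `future`; non-verbs use `n/a`), and flags for "to be" forms and the
#' possessive "my". A real-language tagger can be plugged in by producing a
#' table with the same schema.
#'
#' @param path file path to the CSV.
#' @param stemmer optional stemming function applied to the words.
#' @return a tibble with the five columns above.
#' @export
read_tag_lexicon <- function(path, stemmer = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("word", "pos", "tense", "is_to_be", "is_my")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    abort(paste0("Tag lexicon ", path, " is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "onconotes_format_error")
  }
  df$word <- apply_stemmer(as.character(df$word), stemmer)
  df$is_to_be <- as.logical(df$is_to_be)
  df$is_my <- as.logical(df$is_my)
  if (!all(df$pos %in% c("adjective", "verb", "other"))) {
    abort("`pos` must be adjective, verb, or other.",
          class = "onconotes_validation_error")
  }
  verbs <- df$pos == "verb"
  if (!all(df$tense[verbs] %in% c("past", "present", "future"))) {
    abort("Every verb must carry a tense (past/present/future).",
          class = "onconotes_validation_error")
  }
  if (!all(df$tense[!verbs] %in% "n/a")) {
    abort("Non-verbs must have tense 'n/a'.",
          class = "onconotes_validation_error")
  }
  tibble::as_tibble(df[req])
}

#' @rdname read_tag_lexicon
#' @param tags a tag lexicon tibble.
#' @export
write_tag_lexicon <- function(tags, path) {
  readr::write_csv(tags[c("word", "pos", "tense", "is_to_be", "is_my")], path,
                   progress = FALSE)
  invisible(path)
}

#' Per-note word-class counts
#'
#' Classifies every token of every preprocessed note through the tag lexicon
#' and splits adjectives by the sign of their polarity-lexicon entry (+1 ->
#' positive, -1 -> negative, otherwise "other"). Verbs are counted in total
#' and broken down into "to be" forms by tense (past/present/future) and
#' remaining verbs by tense (past/present). The possessive "my" is counted
#' only when the note also mentions a body-related term (`body_terms`,
#' whole-note window); with `body_terms = NULL` every occurrence counts.
#'
#' @param notes preprocessed notes (see [preprocess_notes()]).
#' @param tags tag lexicon tibble (see [read_tag_lexicon()]).
#' @param polarity polarity lexicon tibble (see [read_polarity_lexicon()]).
#' @param body_terms optional character vector of body-related stems gating
#'   the "my" count.
#' @return a tibble with one row per note: `id`, `stage` (if present),
#'   `note_length`, adjective counts (total/positive/negative/other), verb
#'   counts (total, `to_be_past/present/future`, `other_past/present`) and
#'   `my_count`. Empty notes yield all-zero counts.
#' @export
count_word_classes <- function(notes, tags, polarity, body_terms = NULL) {
  assert_preprocessed(notes)
  body_terms <- if (is.null(body_terms)) NULL else unique(body_terms)
  one <- function(tokens) {
    n <- length(tokens)
    ti <- match(tokens, tags$word)
    pos <- ifelse(is.na(ti), "none", tags$pos[ti])
    tense <- ifelse(is.na(ti), "n/a", tags$tense[ti])
    tobe <- !is.na(ti) & tags$is_to_be[ti]
    my <- !is.na(ti) & tags$is_my[ti]
    pol <- polarity$polarity[match(tokens, polarity$word)]
    adj <- pos == "adjective"
    my_raw <- sum(my)
    my_count <- if (is.null(body_terms)) {
      my_raw
    } else if (any(tokens %in% body_terms)) my_raw else 0L
    tibble::tibble(
      note_length = n,
      adjectives_total = sum(adj),
      adjectives_positive = sum(adj & !is.na(pol) & pol == 1L),
      adjectives_negative = sum(adj & !is.na(pol) & pol == -1L),
      verbs_total = sum(pos == "verb"),
      to_be_past = sum(tobe & tense == "past"),
      to_be_present = sum(tobe & tense == "present"),
      to_be_future = sum(tobe & tense == "future"),
      other_past = sum(pos == "verb" & !tobe & tense == "past"),
      other_present = sum(pos == "verb" & !tobe & tense == "present"),
      my_count = as.integer(my_count)
    )
  }
  counts <- dplyr::bind_rows(lapply(notes$tokens, one))
  counts$adjectives_other <-
    counts$adjectives_total - counts$adjectives_positive -
    counts$adjectives_negative
  front <- notes[intersect(c("id", "stage"), names(notes))]
  out <- dplyr::bind_cols(front, counts)
  dplyr::relocate(out, "adjectives_other",
                  .after = "adjectives_negative")
}

#' Adjective saturation of a note
#'
#' The percentage of a note's tokens that are negative (resp. positive)
#' adjectives: `100 * adjectives_negative / note_length` and likewise for
#' positive. Undefined for empty notes.
#'
#' @param counts word-class counts tibble (see [count_word_classes()]).
#' @return `counts` with `negative_pct` and `positive_pct` columns added.
#' @export
adjective_saturation <- function(counts) {
  if (!all(c("note_length", "adjectives_negative", "adjectives_positive")
           %in% names(counts))) {
    abort("`counts` must come from count_word_classes().",
          class = "onconotes_input_error")
  }
  zero <- counts$note_length == 0
  if (any(zero)) {
    ids <- if ("id" %in% names(counts)) counts$id[zero] else which(zero)
    abort(paste0("Adjective saturation undefined for empty note(s): ",
                 paste(head(ids, 5), collapse = ", ")),
          class = "onconotes_undefined_saturation_error")
  }
  dplyr::mutate(counts,
    negative_pct = 100 * .data$adjectives_negative / .data$note_length,
    positive_pct = 100 * .data$adjectives_positive / .data$note_length
  )
}

#' Mean adjective saturation by treatment stage
#'
#' Unweighted per-note mean of negative and positive adjective saturation
#' within each treatment stage. Stages with no notes are omitted with a
#' warning.
#'
#' @param saturation output of [adjective_saturation()]; must carry a
#'   `stage` column.
#' @return a tibble with columns `stage`, `n`, `mean_negative_pct`,
#'   `mean_positive_pct`.
#' @export
stage_adjective_means <- function(saturation) {
  if (!"stage" %in% names(saturation)) {
    abort("`saturation` must carry a `stage` column.",
          class = "onconotes_input_error")
  }
  warn_empty_stages(saturation$stage)
  saturation |>
    dplyr::mutate(stage = factor(.data$stage, levels = stage_levels())) |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_negative_pct = mean(.data$negative_pct),
      mean_positive_pct = mean(.data$positive_pct),
      .groups = "drop"
    ) |>
    dplyr::mutate(stage = as.character(.data$stage))
}
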