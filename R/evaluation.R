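# Method-versus-expert agreement: Cohen's kappa with full confusion
# bookkeeping, per-stage agreement breakdowns with discrepancy classes, and
# group mean profiles (e.g. pain vs no-pain).

#' Cohen's kappa between two label vectors
#'
#' Unweighted kappa over the union of observed categories:
#' `kappa = (po - pe) / (1 - pe)` with observed agreement `po` and chance
#' agreement `pe` from the marginal distributions. When both raters are
#' constant and identical (`pe = 1`), kappa is defined as 1 and flagged as
#' degenerate. Kappa is symmetric in its arguments and invariant under any
#' relabelling bijection applied to both.
#'
#' @param labels_a,labels_b equal-length category vectors (any atomic type).
#' @return an object of class `agreement_report`: `kappa`,
#'   `observed_agreement`, `expected_agreement`, `confusion` (category x
#'   category count matrix, a rows x b columns), `n`, `degenerate`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("Label vectors must have equal length.",
          class = "onconotes_input_error")
  }
  n <- length(labels_a)
  if (n < 1) {
    abort("Need at least one pair of labels.",
          class = "onconotes_input_error")
  }
  cats <- sort(unique(c(as.character(labels_a), as.character(labels_b))),
               method = "radix")
  fa <- factor(as.character(labels_a), levels = cats)
  fb <- factor(as.character(labels_b), levels = cats)
  confusion <- table(a = fa, b = fb)
  confusion <- matrix(as.integer(confusion), nrow = length(cats),
                      dimnames = list(cats, cats))
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  degenerate <- pe >= 1 - 1e-15
  kappa <- if (degenerate) 1 else (po - pe) / (1 - pe)
  structure(list(kappa = kappa, observed_agreement = po,
                 expected_agreement = pe, confusion = confusion, n = n,
                 degenerate = degenerate),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> n = ", x$n, "\n",
      "  kappa = ", signif(x$kappa, 4),
      " (po = ", signif(x$observed_agreement, 4),
      ", pe = ", signif(x$expected_agreement, 4), ")",
      if (x$degenerate) "  [degenerate: both raters constant]" else "",
      "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) {
  conf <- x$confusion
  tibble::tibble(
    rater_a = rep(rownames(conf), times = ncol(conf)),
    rater_b = rep(colnames(conf), each = nrow(conf)),
    count = as.integer(conf)
  )
}

#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, observed_agreement = x$observed_agreement,
                 expected_agreement = x$expected_agreement, n = x$n,
                 degenerate = x$degenerate)
}

#' Method-versus-expert agreement breakdown by stage
#'
#' Compares method context labels with expert flags per treatment stage.
#' Exact matches are concordant; among discordant notes, the class where the
#' expert rated MIXED but the method favoured one context (POSITIVE or
#' NEGATIVE) is reported separately from plainly incorrect results when
#' `mode = "mixed_lenient"`; in `strict` mode it is folded into the
#' incorrect percentage. The concordant composition (share of each category
#' among concordant notes) is reported alongside.
#'
#' @param data tibble with columns `stage`, `method` (context labels) and
#'   `expert` (flag codes 0/-1/1/2 or context labels).
#' @param mode `strict` or `mixed_lenient`.
#' @return a tibble with one row per observed stage: `stage`, `n`,
#'   `agreement_pct`, `advantage_pct`, `incorrect_pct`, and
#'   `concordant_*_pct` composition columns.
#' @export
agreement_breakdown <- function(data, mode = c("strict", "mixed_lenient")) {
  mode <- match.arg(mode)
  need <- c("stage", "method", "expert")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("`data` is missing column(s): ", paste(miss, collapse = ", ")),
          class = "onconotes_input_error")
  }
  expert <- data$expert
  if (is.numeric(expert)) expert <- flag_to_context(as.integer(expert))
  bad <- setdiff(unique(c(expert, data$method)), context_levels())
  if (length(bad) > 0) {
    abort(paste0("Unknown label(s): ", paste(bad, collapse = ", ")),
          class = "onconotes_input_error")
  }
  df <- tibble::tibble(stage = as.character(data$stage),
                       method = data$method, expert = expert)
  warn_empty_stages(df$stage)
  df$match <- df$method == df$expert
  df$advantage <- !df$match & df$expert == "MIXED" &
    df$method %in% c("POSITIVE", "NEGATIVE")
  df |>
    dplyr::mutate(stage = factor(.data$stage, levels = stage_levels())) |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(
      n = dplyr::n(),
      agreement_pct = 100 * mean(.data$match),
      advantage_pct = if (mode == "mixed_lenient")
        100 * mean(.data$advantage) else 0,
      incorrect_pct = if (mode == "mixed_lenient")
        100 * mean(!.data$match & !.data$advantage) else
          100 * mean(!.data$match),
      concordant_absent_pct = 100 * conc_share(.data$match, .data$expert, "ABSENT"),
      concordant_negative_pct = 100 * conc_share(.data$match, .data$expert, "NEGATIVE"),
      concordant_positive_pct = 100 * conc_share(.data$match, .data$expert, "POSITIVE"),
      concordant_mixed_pct = 100 * conc_share(.data$match, .data$expert, "MIXED"),
      .groups = "drop"
    ) |>
    dplyr::mutate(stage = as.character(.data$stage))
}

# share of one category among concordant notes (0 when none concordant)
conc_share <- function(match, expert, category) {
  if (!any(match)) return(0)
  mean(expert[match] == category)
}

#' Group mean profiles
#'
#' Arithmetic means of every numeric per-note quantity within groups defined
#' by a grouping column (typically the pain flag): the descriptive
#' comparison behind pain versus no-pain profiles.
#'
#' @param data tibble of per-note quantities (e.g. emotion profile joined
#'   with topic affiliations) plus the grouping column.
#' @param group the grouping column (tidy evaluation).
#' @return a tibble with one row per group: the group value, `n`, and the
#'   mean of every numeric column.
#' @export
group_mean_profiles <- function(data, group) {
  grp <- rlang::enquo(group)
  grp_name <- rlang::as_name(grp)
  if (!grp_name %in% names(data)) {
    abort(paste0("Grouping column `", grp_name, "` not found."),
          class = "onconotes_input_error")
  }
  if (anyNA(data[[grp_name]])) {
    warn("Notes with missing group value are dropped.")
    data <- data[!is.na(data[[grp_name]]), , drop = FALSE]
  }
  num_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                      grp_name)
  data |>
    dplyr::group_by(!!grp) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(num_cols), mean),
                     .groups = "drop")
}
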