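# ggplot2 views of the stage-level summaries. Numeric tables remain the
# primary output; these helpers render the standard figures (emotion
# profiles per stage, sentiment splits, adjective saturation).

#' Plot stage-level emotion profiles
#'
#' Radar-style view of the mean five-emotion intensities per treatment
#' stage.
#'
#' @param stage_profiles output of [stage_emotion_profiles()].
#' @return a ggplot object.
#' @export
plot_stage_emotion_profiles <- function(stage_profiles) {
  long <- tidyr::pivot_longer(stage_profiles,
                              cols = dplyr::all_of(emotion_labels()),
                              names_to = "emotion", values_to = "intensity")
  long$emotion <- factor(long$emotion, levels = emotion_labels())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$emotion, y = .data$intensity,
                                     group = .data$stage,
                                     colour = .data$stage)) +
    ggplot2::geom_polygon(ggplot2::aes(fill = .data$stage), alpha = 0.1,
                          show.legend = FALSE) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "mean intensity",
                  colour = "stage",
                  title = "Emotion profiles by treatment stage") +
    ggplot2::theme_minimal()
}

#' Plot the sentiment breakdown per stage
#'
#' Stacked percentage bars of positive/neutral/negative note shares.
#'
#' @param breakdown output of [stage_sentiment_breakdown()].
#' @return a ggplot object.
#' @export
plot_stage_sentiment <- function(breakdown) {
  long <- tidyr::pivot_longer(breakdown,
                              cols = c("pct_positive", "pct_neutral",
                                       "pct_negative"),
                              names_to = "polarity", values_to = "pct")
  long$polarity <- factor(sub("pct_", "", long$polarity),
                          levels = c("negative", "neutral", "positive"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$pct,
                                     fill = .data$polarity)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "treatment stage", y = "% of notes",
                  title = "Sentiment polarity by treatment stage") +
    ggplot2::theme_minimal()
}

#' Plot mean adjective saturation per stage
#'
#' Side-by-side bars of the mean negative and positive adjective
#' percentages of note length.
#'
#' @param stage_means output of [stage_adjective_means()].
#' @return a ggplot object.
#' @export
plot_adjective_saturation <- function(stage_means) {
  long <- tidyr::pivot_longer(stage_means,
                              cols = c("mean_negative_pct",
                                       "mean_positive_pct"),
                              names_to = "kind", values_to = "pct")
  long$kind <- sub("mean_(.*)_pct", "\\1 adjectives", long$kind)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$pct,
                                     fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "treatment stage", y = "% of note length",
                  fill = NULL,
                  title = "Adjective saturation by treatment stage") +
    ggplot2::theme_minimal()
}

#' @describeIn cohens_kappa heatmap of the confusion matrix behind an
#'   agreement report.
#' @param object an `agreement_report`.
#' @param ... unused.
#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rater_b, y = .data$rater_a,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "expert", y = "method",
                  title = sprintf("Agreement (kappa = %.2f, n = %d)",
                                  object$kappa, object$n)) +
    ggplot2::theme_minimal()
}
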