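# ggplot2 displays for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Confusion-matrix heatmap
#'
#' @param object a `stage_eval` from [evaluate_staging()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.stage_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$cm))
  names(df) <- c("truth", "predicted", "n")
  df <- df |>
    dplyr::group_by(.data$truth) |>
    dplyr::mutate(frac = .data$n / max(1, sum(.data$n))) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$frac)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$cm))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 name = "row fraction") +
    ggplot2::labs(
      x = "predicted stage", y = "expert stage",
      title = sprintf("accuracy %.1f%%, macro-F1 %.1f, kappa %.2f",
                      object$accuracy, object$macro_f1, object$kappa)
    ) +
    ggplot2::theme_minimal()
}

#' Fisher-score / selection overview
#'
#' Scores in descending order with the prefilter threshold; selected
#' features highlighted.
#'
#' @param object a `feature_selection` from [select_features()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.feature_selection <- function(object, ...) {
  df <- object$scores |>
    dplyr::arrange(dplyr::desc(.data$j)) |>
    dplyr::mutate(ord = dplyr::row_number(),
                  j_plot = pmin(.data$j, max(.data$j[is.finite(.data$j)])))
  ggplot2::ggplot(df, ggplot2::aes(.data$ord, .data$j_plot,
                                   colour = .data$selected)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "feature (descending score)", y = "Fisher score",
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' Hypnogram plot
#'
#' Stage-versus-time staircase for one subject-night, from the metadata of
#' an epoch set or a prediction tibble.
#'
#' @param meta tibble with `epoch_index` and `stage` columns (already
#'   filtered to one subject-night).
#' @param epoch_s epoch length in seconds.
#' @return a ggplot.
#' @export
plot_hypnogram <- function(meta, epoch_s = 30) {
  ord <- c("N3", "N2", "N1", "REM", "W")
  df <- dplyr::mutate(meta,
                      hours = .data$epoch_index * epoch_s / 3600,
                      stage_f = factor(.data$stage, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(.data$hours, .data$stage_f, group = 1)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (h)", y = "stage") +
    ggplot2::theme_minimal()
}
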