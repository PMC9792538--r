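#' Plot a generalized-dimension spectrum
#'
#' `D_q` against the moment order `q`; multifractal measures show a
#' decreasing sigmoid, monofractals a flat line.
#'
#' @param object An `mf_genspec`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mf_genspec <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$q, .data$Dq)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "moment order q", y = expression(D[q]),
                  title = "Generalized dimensions") +
    ggplot2::theme_minimal()
}

#' Plot a singularity spectrum
#'
#' `f(alpha)` against the Hoelder exponent `alpha`; spectrum width and
#' asymmetry are the staging-relevant shape features.
#'
#' @param object An `mf_singularity`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mf_singularity <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$alpha, .data$f_alpha)) +
    ggplot2::geom_path(colour = "firebrick") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(alpha), y = expression(f(alpha)),
                  title = "Singularity spectrum") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mf_singularity
#' @export
autoplot.mf_spectrum <- function(object, ...) {
  autoplot.mf_singularity(object$singularity, ...) +
    ggplot2::labs(subtitle = sprintf(
      "D0 = %.3f, D1 = %.3f, D2 = %.3f",
      named_dimensions(object$dimensions)["D0"],
      named_dimensions(object$dimensions)["D1"],
      named_dimensions(object$dimensions)["D2"]
    ))
}

#' Plot a ROC curve
#'
#' @param object An `mf_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mf_roc <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-run evaluation accuracy
#'
#' @param object A `knn_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.knn_eval <- function(object, ...) {
  ggplot2::ggplot(object$runs, ggplot2::aes(.data$run, .data$accuracy)) +
    ggplot2::geom_hline(yintercept = object$summary$mean_accuracy,
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::scale_x_continuous(breaks = object$runs$run) +
    ggplot2::labs(x = "run", y = "test accuracy (%)",
                  title = sprintf("Split-and-average evaluation (mean %.2f%%)",
                                  object$summary$mean_accuracy)) +
    ggplot2::theme_minimal()
}

#' Stage-wise feature distributions
#'
#' Boxplots of each feature by stage, one free-scale facet per feature — the
#' visual check that the ten features separate the stages.
#'
#' @param data Labeled feature tibble (columns [mf_feature_names] plus the
#'   label column).
#' @param label_col Label column name (default `"stage"`).
#' @return A ggplot.
#' @export
plot_feature_trends <- function(data, label_col = "stage") {
  long <- tidyr::pivot_longer(
    as_tibble(data),
    cols = dplyr::any_of(mf_feature_names),
    names_to = "feature", values_to = "value"
  )
  long$feature <- factor(long$feature, levels = mf_feature_names)
  ggplot2::ggplot(long, ggplot2::aes(.data[[label_col]], .data$value,
                                     fill = .data[[label_col]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Feature distributions by stage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
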