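# Optional ggplot2 visualisations of the evaluation curves.

#' Plot a recall-precision curve
#'
#' Precision against recall with the random-classifier baseline (the
#' positive fraction) drawn as a dashed horizontal line.
#'
#' @param pr a [pr_curve()] result.
#' @return A ggplot object.
#' @export
plot_pr_curve <- function(pr) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  keep <- pr$recall > 0 | pr$precision > 0
  ggplot2::ggplot(pr[keep, ], ggplot2::aes(x = recall,
                                           y = precision)) +
    ggplot2::geom_line(linewidth = 0.7, colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = attr(pr, "baseline"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision (PPV)",
                  subtitle = sprintf("AUC = %.3f, baseline = %.3f",
                                     attr(pr, "auc"), attr(pr, "baseline"))) +
    ggplot2::theme_minimal()
}

#' Plot PPV, recall and F1 against the score cutoff
#'
#' The conventional score-plot overlay: the three measures as functions
#' of the prediction-score cutoff, with the F1-maximizing cutoff marked.
#'
#' @param sp a [score_plot()] result.
#' @return A ggplot object.
#' @export
plot_score_curves <- function(sp) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  long <- data.frame(
    cutoff = rep(sp$cutoff, 3),
    value = c(sp$ppv, sp$recall, sp$f1),
    measure = rep(c("PPV", "recall", "F1"), each = nrow(sp))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = cutoff, y = value,
                                     colour = measure,
                                     linetype = measure)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = attr(sp, "best_cutoff"),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "Score cutoff", y = "Measure", colour = NULL,
                  linetype = NULL) +
    ggplot2::theme_minimal()
}
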