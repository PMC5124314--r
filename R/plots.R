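#' Plot a ROC curve
#'
#' @param object A `cleav_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cleav_roc
#' @export
autoplot.cleav_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    )
}

#' Plot the decision-score profile of a precursor scan
#'
#' Scores along the hairpin, with the predicted cleavage sites marked.
#'
#' @param object A `cleav_scan` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cleav_scan
#' @export
autoplot.cleav_scan <- function(object, ...) {
  pred <- object$pred[!is.na(object$pred$site), ]
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$site, y = .data$score,
                               colour = .data$side)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::geom_vline(data = pred, ggplot2::aes(xintercept = .data$site),
                        linetype = "dotted") +
    ggplot2::labs(
      x = "Inter-nucleotide site", y = "SVM decision score", colour = "Side",
      title = if (!is.na(object$id)) paste("Scan of", object$id) else "Scan"
    )
}

#' Plot a cumulative end-absolute-error profile
#'
#' @param object A `cleav_eae` tibble from [eae_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cleav_eae
#' @export
autoplot.cleav_eae <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$frac)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "EAE threshold t (nt)",
                  y = "Fraction of predictions with EAE ≤ t")
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `cleav_cv` object.
#' @param ... Unused.
#' @return A ggplot with one panel per metric.
#' @method autoplot cleav_cv
#' @export
autoplot.cleav_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_fold,
                              dplyr::all_of(c("sn", "sp", "ac", "mcc")),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$arm, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Arm", y = "Per-fold value")
}
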