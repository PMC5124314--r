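#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-fold cross-validation results
#'
#' @param x A `cleav_cv` object.
#' @param ... Unused.
#' @return A tibble with one row per arm and fold: confusion counts and
#'   Sn/Sp/Ac/MCC.
#' @method tidy cleav_cv
#' @export
tidy.cleav_cv <- function(x, ...) {
  x$per_fold
}

#' One-row-per-arm summary of a cross-validation
#'
#' @param x A `cleav_cv` object.
#' @param ... Unused.
#' @return A tibble with one row per arm: mean `sn`, `sp`, `ac`, `mcc`
#'   across folds, their sample variances (`var_*`), the pooled `auc` and
#'   the number of `folds`.
#' @method glance cleav_cv
#' @export
glance.cleav_cv <- function(x, ...) {
  means <- x$summary |>
    dplyr::select(!"variance") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "mean")
  vars <- x$summary |>
    dplyr::select(!"mean") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "variance",
                       names_prefix = "var_")
  dplyr::inner_join(means, vars, by = "arm") |>
    dplyr::inner_join(x$auc, by = "arm") |>
    dplyr::mutate(folds = x$params$folds) |>
    dplyr::select(dplyr::all_of(c("arm", "sn", "sp", "ac", "mcc",
                                  "var_sn", "var_sp", "var_ac", "var_mcc",
                                  "auc", "folds")))
}

#' Tidy the threshold sweep of a ROC curve
#'
#' @param x A `cleav_roc` object.
#' @param ... Unused.
#' @return The `threshold`, `fpr`, `tpr` tibble.
#' @method tidy cleav_roc
#' @export
tidy.cleav_roc <- function(x, ...) {
  x$points
}

#' @rdname tidy.cleav_roc
#' @method glance cleav_roc
#' @export
glance.cleav_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_thresholds = nrow(x$points) - 1L)
}

#' Tidy a fitted cleavage-site model
#'
#' @param x A `cleav_model`.
#' @param ... Unused.
#' @return A tibble with the number of support vectors per class.
#' @method tidy cleav_model
#' @export
tidy.cleav_model <- function(x, ...) {
  tibble::tibble(
    class = as.integer(x$svm$levels[x$svm$labels]),
    n_support = x$svm$nSV
  )
}

#' @rdname tidy.cleav_model
#' @method glance cleav_model
#' @export
glance.cleav_model <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme$name, w = x$scheme$w, k = x$scheme$k,
    M = if (is.null(x$scheme$M)) NA_integer_ else x$scheme$M,
    kernel = x$kernel, gamma = x$gamma, cost = x$cost,
    n_train = x$n_train, dim = x$dim, n_support = sum(x$svm$nSV)
  )
}

#' Tidy a precursor scan
#'
#' @param x A `cleav_scan` object.
#' @param ... Unused.
#' @return The per-site score profile (`site`, `side`, `score`).
#' @method tidy cleav_scan
#' @export
tidy.cleav_scan <- function(x, ...) {
  x$profile
}

#' @rdname tidy.cleav_scan
#' @method glance cleav_scan
#' @export
glance.cleav_scan <- function(x, ...) {
  tibble::tibble(
    id = x$id,
    cd5p_pred = x$pred$site[x$pred$arm == "5p"],
    cd3p_pred = x$pred$site[x$pred$arm == "3p"],
    score5p = x$pred$score[x$pred$arm == "5p"],
    score3p = x$pred$score[x$pred$arm == "3p"],
    n_sites = nrow(x$profile)
  )
}
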