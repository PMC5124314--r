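#' Fit one SVM per arm
#'
#' The 5p and 3p arms present systematically different window patterns (the
#' planted or biological cue sits on opposite sides of the cut), so site
#' scanning uses an arm-specific model pair: windows on the 5p side of the
#' apex are scored by the 5p model, windows on the 3p side by the 3p model.
#'
#' @inheritParams cleav_fit
#' @return A `cleav_model_set`: list of `cleav_model` objects named by arm.
#' @export
cleav_fit_arms <- function(windows, scheme, gamma = NULL, cost = 1,
                           kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  arms <- intersect(c("5p", "3p"), unique(windows$arm))
  if (length(arms) == 0L) stop("no windows to fit", call. = FALSE)
  models <- purrr::map(
    stats::setNames(arms, arms),
    ~ cleav_fit(windows[windows$arm == .x, ], scheme,
                gamma = gamma, cost = cost, kernel = kernel)
  )
  structure(list(models = models), class = "cleav_model_set")
}

#' @export
print.cleav_model_set <- function(x, ...) {
  cat("<cleav_model_set> per-arm models:\n")
  for (a in names(x$models)) {
    cat("  [", a, "] ", sep = "")
    print(x$models[[a]])
  }
  invisible(x)
}

#' @method glance cleav_model_set
#' @export
glance.cleav_model_set <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(
    x$models,
    ~ dplyr::mutate(glance(.x), arm = .y, .before = 1)
  ))
}
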