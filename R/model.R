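#' Classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any factor
#' of the MCC denominator is zero the MCC is defined as 0.
#'
#' @param tp,tn,fp,fn Non-negative integer counts; vectorized.
#' @return A tibble with columns `sn`, `sp`, `ac`, `mcc`.
#' @examples
#' compute_metrics(tp = 8, tn = 7, fp = 2, fn = 3)
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  if (any(total == 0)) stop("no evaluated examples", call. = FALSE)
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  tibble::tibble(
    sn = tp / (tp + fn),
    sp = tn / (tn + fp),
    ac = (tp + tn) / total,
    mcc = ifelse(denom == 0, 0, (tp * tn - fp * fn) / denom)
  )
}

# confusion counts from +1/-1 predictions and labels
confusion_counts <- function(pred, label) {
  list(tp = sum(pred == 1 & label == 1), tn = sum(pred == -1 & label == -1),
       fp = sum(pred == 1 & label == -1), fn = sum(pred == -1 & label == 1))
}

#' Fit an SVM on encoded cleavage-site windows
#'
#' Encodes the windows under `scheme` and fits a soft-margin SVM (via
#' libSVM, through \pkg{e1071}). The default kernel is the radial basis
#' function `exp(-gamma ||x1 - x2||^2)`; with the lbsize encoding the kernel
#' between two loop tokens then decays as `exp(-2 gamma min(|l1-l2|, k))`.
#'
#' @param windows A windows tibble from [make_windows()] (both classes must
#'   be present).
#' @param scheme An `encoding_scheme`; an unresolved lbsize `M` is fixed
#'   from these (training) windows.
#' @param gamma RBF width; default `1 / feature dimension`.
#' @param cost Soft-margin cost `C` (default 1).
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @return A `cleav_model` object.
#' @export
cleav_fit <- function(windows, scheme, gamma = NULL, cost = 1,
                      kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  feats <- if (inherits(windows, "cleav_features")) windows
           else encode_windows(windows, scheme)
  if (length(unique(feats$y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  gamma <- if (is.null(gamma)) 1 / ncol(feats$x) else gamma
  fit <- e1071::svm(
    x = feats$x, y = factor(feats$y, levels = c(-1, 1)),
    type = "C-classification",
    kernel = if (kernel == "rbf") "radial" else "linear",
    gamma = gamma, cost = cost, scale = FALSE
  )
  structure(
    list(scheme = feats$scheme, kernel = kernel, gamma = gamma, cost = cost,
         svm = fit, n_train = nrow(feats$x), dim = ncol(feats$x)),
    class = "cleav_model"
  )
}

#' @export
print.cleav_model <- function(x, ...) {
  cat("<cleav_model> ", x$kernel, "-kernel SVM on ", x$scheme$name,
      " features (w = ", x$scheme$w,
      if (x$scheme$name == "lbsize") paste0(", k = ", x$scheme$k, ", M = ", x$scheme$M),
      "), ", x$n_train, " training windows, dim ", x$dim,
      ", gamma = ", signif(x$gamma, 3), ", cost = ", x$cost, "\n", sep = "")
  invisible(x)
}

# decision scores oriented so that positive score => class +1
decision_scores <- function(model, x) {
  if (nrow(x) == 0L) return(numeric(0))
  pred <- stats::predict(model$svm, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  sgn <- if (strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1] == "1") 1 else -1
  unname(sgn * dv[, 1])
}

#' Predict labels and decision scores for windows
#'
#' @param object A `cleav_model`.
#' @param windows A windows tibble; encoded under the model's (training)
#'   scheme, so the training `M` is reused and longer loops are clipped.
#' @param ... Unused.
#' @return The window metadata tibble with `score` (real-valued decision
#'   value, positive favoring a cleavage site) and `pred` (+1/-1) appended.
#' @export
predict.cleav_model <- function(object, windows, ...) {
  feats <- if (inherits(windows, "cleav_features")) windows
           else encode_windows(windows, object$scheme)
  score <- decision_scores(object, feats$x)
  out <- feats$meta
  out$score <- score
  out$pred <- ifelse(score > 0, 1L, -1L)
  out
}

#' Empirical ROC curve and AUC from decision scores
#'
#' Sweeps a threshold over the distinct score values (ties grouped), from
#' `(0, 0)` to `(1, 1)`, and integrates the curve by the trapezoid rule.
#'
#' @param scores Real-valued decision scores (higher favors the positive
#'   class).
#' @param labels Labels in \{+1, -1\}.
#' @return A `cleav_roc` object: list with `points` (tibble `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  y <- as.integer(labels) == 1L
  if (all(y) || !any(y)) stop("both classes required for a ROC curve", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(!y))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(points = tibble::tibble(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr),
         auc = auc),
    class = "cleav_roc"
  )
}

#' @export
print.cleav_roc <- function(x, ...) {
  cat("<cleav_roc> ", nrow(x$points), " points, AUC = ",
      signif(x$auc, 4), "\n", sep = "")
  invisible(x)
}

#' Fivefold cross-validated evaluation, split by precursor
#'
#' Precursors (never individual windows) are shuffled with `seed` and dealt
#' round-robin into folds, so a precursor's positive and negative windows —
#' which overlap heavily in sequence — can never straddle the train/test
#' boundary. The 5p and 3p arms are evaluated separately. For the lbsize
#' scheme, `M` is resolved on each fold's training windows unless fixed in
#' the scheme. Reported per arm: per-fold Sn/Sp/Ac/MCC, their mean and
#' sample variance (n-1 denominator), and a ROC with AUC pooled over the
#' held-out decision scores of all folds.
#'
#' @inheritParams cleav_fit
#' @param folds Number of folds (default 5).
#' @param seed Integer seed governing the fold shuffle.
#' @return A `cleav_cv` object; see [tidy.cleav_cv()] and
#'   [glance.cleav_cv()]. Its `folds_assignment` element records which fold
#'   held out each precursor, so the no-leakage property can be audited.
#' @export
cross_validate <- function(windows, scheme, folds = 5L, gamma = NULL, cost = 1,
                           seed = 1L, kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  arms <- sort(unique(windows$arm), decreasing = TRUE)  # "5p" before "3p"
  per_fold <- list(); rocs <- list(); aucs <- list(); assignments <- list()
  for (a in arms) {
    aw <- windows[windows$arm == a, ]
    ids <- unique(aw$id)
    if (length(ids) < folds) {
      stop("arm ", a, ": fewer precursors (", length(ids),
           ") than folds (", folds, ")", call. = FALSE)
    }
    shuffled <- withr::with_seed(seed, sample(ids))
    fold_of <- stats::setNames(rep(seq_len(folds), length.out = length(shuffled)),
                               shuffled)
    assignments[[length(assignments) + 1L]] <-
      tibble::tibble(arm = a, id = names(fold_of), fold = unname(fold_of))
    scores <- numeric(0); score_labels <- integer(0)
    for (f in seq_len(folds)) {
      test_ids <- names(fold_of)[fold_of == f]
      train <- aw[!aw$id %in% test_ids, ]
      test <- aw[aw$id %in% test_ids, ]
      stopifnot(length(intersect(unique(train$id), unique(test$id))) == 0L)
      model <- cleav_fit(train, scheme, gamma = gamma, cost = cost, kernel = kernel)
      pred <- suppressWarnings(predict(model, test))
      cc <- confusion_counts(pred$pred, pred$label)
      per_fold[[length(per_fold) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(arm = a, fold = f,
                       tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn),
        compute_metrics(cc$tp, cc$tn, cc$fp, cc$fn)
      )
      scores <- c(scores, pred$score)
      score_labels <- c(score_labels, pred$label)
    }
    rocs[[a]] <- roc_curve(scores, score_labels)
    aucs[[length(aucs) + 1L]] <- tibble::tibble(arm = a, auc = rocs[[a]]$auc)
  }
  per_fold <- dplyr::bind_rows(per_fold)
  summary <- per_fold |>
    tidyr::pivot_longer(dplyr::all_of(c("sn", "sp", "ac", "mcc")),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$arm, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     variance = stats::var(.data$value), .groups = "drop")
  structure(
    list(per_fold = per_fold, summary = summary, roc = rocs,
         auc = dplyr::bind_rows(aucs),
         folds_assignment = dplyr::bind_rows(assignments),
         params = list(scheme = scheme, folds = folds, gamma = gamma,
                       cost = cost, seed = seed, kernel = kernel)),
    class = "cleav_cv"
  )
}

#' @export
print.cleav_cv <- function(x, ...) {
  sc <- x$params$scheme
  cat("<cleav_cv> ", x$params$folds, "-fold cross-validation, ",
      sc$name, " encoding (w = ", sc$w,
      if (sc$name == "lbsize") paste0(", k = ", sc$k), ")\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Sweep window sizes and k over a fivefold evaluation grid
#'
#' Re-extracts windows for each window size and cross-validates every
#' requested encoding scheme, with `k` varied for the lbsize scheme only —
#' the protocol behind the paper-style summary table (mean metrics per
#' method, window size and arm).
#'
#' @param precursors A precursors tibble.
#' @param ws Window sizes to sweep (default `c(8, 10, 12, 14)`).
#' @param ks lbsize `k` values to sweep (default `1:5`).
#' @param schemes Scheme names to include.
#' @param offset,direction Passed to [make_windows()].
#' @inheritParams cross_validate
#' @return A tibble: `scheme`, `w`, `k`, `arm`, mean `sn`, `sp`, `ac`,
#'   `mcc` and their fold variances, plus `auc`.
#' @export
scheme_grid_eval <- function(precursors, ws = c(8L, 10L, 12L, 14L), ks = 1:5,
                             schemes = c("seq", "struct", "extended", "lbsize"),
                             offset = 6L, direction = "toward-apex",
                             folds = 5L, gamma = NULL, cost = 1, seed = 1L) {
  combos <- dplyr::bind_rows(purrr::map(ws, function(w) {
    dplyr::bind_rows(purrr::map(schemes, function(s) {
      if (s == "lbsize") tibble::tibble(scheme = s, w = w, k = as.integer(ks))
      else tibble::tibble(scheme = s, w = w, k = NA_integer_)
    }))
  }))
  win_cache <- stats::setNames(
    purrr::map(ws, ~ make_windows(precursors, .x, offset = offset,
                                  direction = direction)),
    as.character(ws)
  )
  purrr::pmap_dfr(combos, function(scheme, w, k) {
    sc <- if (scheme == "lbsize") encoding_scheme("lbsize", w = w, k = k)
          else encoding_scheme(scheme, w = w)
    cv <- cross_validate(win_cache[[as.character(w)]], sc, folds = folds,
                         gamma = gamma, cost = cost, seed = seed)
    g <- glance(cv)
    dplyr::bind_cols(tibble::tibble(scheme = scheme, w = w, k = k), g)
  })
}
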