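#' Scan a precursor for cleavage sites with a shift window
#'
#' Slides a window of the model's training width across every
#' inter-nucleotide site admitting a full window and records the SVM
#' decision score. The predicted CD-5p is the highest-scoring site on the
#' 5p side of the apex, the predicted CD-3p the highest-scoring site on the
#' 3p side; ties go to the 5'-most site. Sites whose window faces no base
#' pair get an all-gap complementary segment.
#'
#' @param model A `cleav_model`, or a `cleav_model_set` from
#'   [cleav_fit_arms()] (then each side of the apex is scored by its own
#'   arm's model; apex-straddling sites get `NA`).
#' @param seq RNA sequence of the precursor.
#' @param db Its dot-bracket structure.
#' @param id Optional precursor id carried into the result.
#' @return A `cleav_scan` object: list with `profile` (tibble `site`,
#'   `side`, `score`) and `pred` (tibble `arm`, `site`, `score`).
#' @export
scan_precursor <- function(model, seq, db, id = NA_character_) {
  models <- if (inherits(model, "cleav_model_set")) model$models
            else list(pooled = model)
  ws <- unique(vapply(models, function(m) m$scheme$w, integer(1)))
  if (length(ws) != 1L) stop("arm models disagree on window size", call. = FALSE)
  w <- ws
  seq <- gsub("T", "U", toupper(seq), fixed = TRUE)
  n <- nchar(seq)
  if (n < w) stop("precursor shorter than window size ", w, call. = FALSE)
  pm <- parse_dotbracket(db)
  loops <- annotate_loops(pm)
  apex <- find_apex(pm)
  sites <- (w %/% 2L):(n - w %/% 2L)
  rows <- purrr::map(sites, function(s) {
    win <- extract_window(s, w, seq, loops)
    seg <- tryCatch(complementary_segment(win$pos[1], w, pm, apex),
                    error = function(e) rep(NA_integer_, w))
    cmp <- comp_tokens(seg, seq, loops)
    tibble::tibble(
      id = id, arm = NA_character_, label = NA_integer_, center = s,
      arm_nt = list(win$nt), arm_l = list(win$l),
      comp_nt = list(cmp$nt), comp_l = list(cmp$l),
      arm_tokens = render_tokens(win$nt, win$l),
      comp_tokens = render_tokens(cmp$nt, cmp$l)
    )
  })
  windows <- dplyr::bind_rows(rows)
  side <- ifelse(sites < apex$apex_start, "5p",
                 ifelse(sites >= apex$apex_end, "3p", "apex"))
  score_with <- function(m) {
    feats <- suppressWarnings(encode_windows(windows, m$scheme))
    decision_scores(m, feats$x)
  }
  if (length(models) == 1L && names(models)[1] == "pooled") {
    score <- score_with(models$pooled)
  } else {
    score <- rep(NA_real_, length(sites))
    for (a in names(models)) {
      hit <- side == a
      if (any(hit)) score[hit] <- score_with(models[[a]])[hit]
    }
  }
  profile <- tibble::tibble(site = sites, side = side, score = score)
  pick <- function(arm) {
    cand <- profile[profile$side == arm & !is.na(profile$score), ]
    if (nrow(cand) == 0L) {
      return(tibble::tibble(arm = arm, site = NA_integer_, score = NA_real_))
    }
    best <- cand[order(-cand$score, cand$site), ][1, ]
    tibble::tibble(arm = arm, site = best$site, score = best$score)
  }
  structure(
    list(id = id, profile = profile,
         pred = dplyr::bind_rows(pick("5p"), pick("3p"))),
    class = "cleav_scan"
  )
}

#' @export
print.cleav_scan <- function(x, ...) {
  cat("<cleav_scan> ", nrow(x$profile), " sites",
      if (!is.na(x$id)) paste0(" (", x$id, ")"), "\n", sep = "")
  print(x$pred)
  invisible(x)
}

#' Predict cleavage sites for a set of precursors
#'
#' Runs [scan_precursor()] on every row; precursors too short for the
#' model's window are reported with `NA` predictions and a warning.
#'
#' @param model A `cleav_model`.
#' @param precursors A precursors tibble.
#' @return A tibble `id`, `arm`, `site`, `score` (two rows per precursor).
#' @export
predict_sites <- function(model, precursors) {
  purrr::pmap_dfr(precursors[, c("id", "seq", "db")], function(id, seq, db) {
    sc <- tryCatch(scan_precursor(model, seq, db, id = id),
                   error = function(e) e)
    if (inherits(sc, "error")) {
      warning("scan failed for ", id, ": ", conditionMessage(sc), call. = FALSE)
      return(tibble::tibble(id = id, arm = c("5p", "3p"),
                            site = NA_integer_, score = NA_real_))
    }
    dplyr::bind_cols(tibble::tibble(id = id), sc$pred)
  })
}

#' End absolute error between a predicted and a true cleavage site
#'
#' @param predicted,true Inter-nucleotide site indices; vectorized.
#' @return `|predicted - true|`, in nucleotides.
#' @export
end_absolute_error <- function(predicted, true) {
  abs(predicted - true)
}

#' Cumulative end-absolute-error profile
#'
#' Fraction of predictions whose EAE is at most `t`, for `t = 0, 1, 2, ...`
#' up to the largest observed error; non-decreasing and reaching 1.
#'
#' @param errors Vector of non-negative EAEs (NAs are dropped with a
#'   warning).
#' @param t_max Largest threshold reported; defaults to the largest observed
#'   error (always at least `t_max` rows when supplied, e.g. for perfect
#'   predictions).
#' @return A `cleav_eae` tibble with columns `t` and `frac`.
#' @export
eae_profile <- function(errors, t_max = NULL) {
  if (anyNA(errors)) {
    warning(sum(is.na(errors)), " undefined EAE value(s) dropped", call. = FALSE)
    errors <- errors[!is.na(errors)]
  }
  stopifnot(length(errors) > 0L, all(errors >= 0))
  ts <- 0:max(errors, t_max)
  out <- tibble::tibble(
    t = ts,
    frac = vapply(ts, function(t) mean(errors <= t), numeric(1))
  )
  class(out) <- c("cleav_eae", class(out))
  out
}
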