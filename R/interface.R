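#' Generate a synthetic dataset directory
#'
#' Convenience wrapper tying [generate_dataset()] to
#' [write_synthetic_dataset()]; the workflow entry point behind the
#' `simulate` subcommand of the command-line script.
#'
#' @param dir Output directory.
#' @param params A `synth_params` list.
#' @return Invisibly, the written paths.
#' @export
run_simulate <- function(dir, params = synth_params()) {
  ds <- generate_dataset(params)
  paths <- write_synthetic_dataset(ds, dir)
  message("wrote ", nrow(ds), " synthetic precursors to ", dir)
  invisible(paths)
}

# resolved configuration written next to every report
write_config <- function(dir, config) {
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Encode a precursor dataset into labeled windows and feature files
#'
#' Loads sequences/structures and mature-arm coordinates, builds the
#' positive/negative windows, resolves the dataset-wide maximum loop length
#' `M`, and writes a windows TSV plus one sparse SVM-light feature file per
#' arm together with a JSON scheme descriptor.
#'
#' @param vienna Path to a Vienna dot-bracket file.
#' @param annotation Path to the mature-arm annotation TSV.
#' @param out_dir Output directory (created if missing).
#' @param scheme Scheme name (`"lbsize"`, `"seq"`, `"struct"`,
#'   `"extended"`).
#' @param w Even window size.
#' @param k lbsize loop-token width.
#' @param offset,direction Negative-window placement; see [make_windows()].
#' @return Invisibly, a list with the windows tibble, per-arm
#'   `cleav_features` and the resolved scheme.
#' @export
run_encode <- function(vienna, annotation, out_dir,
                       scheme = "lbsize", w = 10L, k = 3L,
                       offset = 6L, direction = "toward-apex") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pre <- load_precursors(vienna, annotation)
  windows <- make_windows(pre, w = w, offset = offset, direction = direction)
  sc <- resolve_scheme(encoding_scheme(scheme, w = w, k = k), windows)
  if (sc$name == "lbsize") message("resolved maximum loop length M = ", sc$M)
  write_windows_tsv(windows, file.path(out_dir, "windows.tsv"))
  feats <- list()
  for (a in intersect(c("5p", "3p"), unique(windows$arm))) {
    feats[[a]] <- encode_windows(windows[windows$arm == a, ], sc)
    write_svmlight(feats[[a]], file.path(out_dir, paste0("features_", a, ".svmlight")))
  }
  jsonlite::write_json(
    list(scheme = sc$name, w = sc$w, k = sc$k, M = sc$M),
    file.path(out_dir, "scheme.json"), auto_unbox = TRUE, null = "null"
  )
  write_config(out_dir, list(
    command = "encode", vienna = vienna, annotation = annotation,
    scheme = scheme, w = w, k = k, offset = offset, direction = direction
  ))
  invisible(list(windows = windows, features = feats, scheme = sc))
}

#' Cross-validated training and evaluation
#'
#' Runs the fivefold (by default) precursor-split cross-validation per arm,
#' writes the per-fold and summary report TSV and the pooled ROC points, and
#' fits a final model on all windows of both arms for use in scanning. With
#' `grid = TRUE`, sweeps window sizes 8-14 and `k` 1-5 across the requested
#' schemes and writes one summary table instead.
#'
#' @inheritParams run_encode
#' @param folds,gamma,cost,seed Passed to [cross_validate()]; `seed` also
#'   governs the fold shuffle.
#' @param grid Sweep `w` and `k` instead of a single configuration.
#' @return Invisibly, a list with the `cleav_cv` (or grid tibble) and the
#'   final `cleav_model` (single-configuration mode only).
#' @export
run_train_eval <- function(vienna, annotation, out_dir,
                           scheme = "lbsize", w = 10L, k = 3L,
                           offset = 6L, direction = "toward-apex",
                           folds = 5L, gamma = NULL, cost = 1, seed = 1L,
                           grid = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pre <- load_precursors(vienna, annotation)
  config <- list(command = "train", vienna = vienna, annotation = annotation,
                 scheme = scheme, w = w, k = k, offset = offset,
                 direction = direction, folds = folds, gamma = gamma,
                 cost = cost, seed = seed, grid = grid)
  if (grid) {
    tab <- scheme_grid_eval(pre, offset = offset, direction = direction,
                            folds = folds, gamma = gamma, cost = cost,
                            seed = seed)
    readr::write_tsv(tab, file.path(out_dir, "grid_summary.tsv"))
    write_config(out_dir, config)
    return(invisible(list(grid = tab)))
  }
  windows <- make_windows(pre, w = w, offset = offset, direction = direction)
  sc <- encoding_scheme(scheme, w = w, k = k)
  cv <- cross_validate(windows, sc, folds = folds, gamma = gamma, cost = cost,
                       seed = seed)
  report <- dplyr::bind_rows(
    dplyr::mutate(tidy(cv), row = "fold"),
    dplyr::mutate(glance(cv), row = "summary")
  )
  readr::write_tsv(report, file.path(out_dir, "cv_report.tsv"))
  for (a in names(cv$roc)) {
    readr::write_tsv(cv$roc[[a]]$points,
                     file.path(out_dir, paste0("roc_", a, ".tsv")))
  }
  model <- cleav_fit_arms(windows, sc, gamma = gamma, cost = cost)
  write_model(model, file.path(out_dir, "model.rds"))
  write_config(out_dir, config)
  invisible(list(cv = cv, model = model))
}

#' Scan precursors with a trained model
#'
#' Slides the model's window over every precursor, writes the per-site score
#' profiles and predicted CD-5p/CD-3p sites, and — when a ground-truth table
#' with `cd5p`/`cd3p` columns is supplied — the cumulative end-absolute-
#' error profile.
#'
#' @param model_path Path to a model archive from [write_model()].
#' @param vienna Path to a Vienna dot-bracket file of precursors to scan.
#' @param out_dir Output directory.
#' @param truth Optional path to a TSV with columns `id`, `cd5p`, `cd3p`.
#' @return Invisibly, a list with the predictions tibble, the profiles
#'   tibble, and (if truth was given) the EAE tibbles per arm.
#' @export
run_scan <- function(model_path, vienna, out_dir, truth = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  model <- read_model(model_path)
  pre <- read_vienna(vienna)
  scans <- purrr::pmap(pre, function(id, seq, db) {
    tryCatch(scan_precursor(model, seq, db, id = id), error = function(e) {
      warning("scan failed for ", id, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
  })
  scans <- purrr::compact(scans)
  profiles <- dplyr::bind_rows(
    purrr::map(scans, ~ dplyr::mutate(.x$profile, id = .x$id, .before = 1))
  )
  preds <- dplyr::bind_rows(
    purrr::map(scans, ~ dplyr::mutate(.x$pred, id = .x$id, .before = 1))
  )
  readr::write_tsv(profiles, file.path(out_dir, "scan_profiles.tsv"))
  readr::write_tsv(preds, file.path(out_dir, "predicted_sites.tsv"))
  out <- list(predictions = preds, profiles = profiles)
  if (!is.null(truth)) {
    tt <- readr::read_tsv(truth, col_types = readr::cols())
    joined <- preds |>
      tidyr::pivot_wider(id_cols = "id", names_from = "arm",
                         values_from = "site") |>
      dplyr::inner_join(tt[, c("id", "cd5p", "cd3p")], by = "id")
    errors <- c(end_absolute_error(joined$`5p`, joined$cd5p),
                end_absolute_error(joined$`3p`, joined$cd3p))
    out$eae <- eae_profile(errors)
    readr::write_tsv(out$eae, file.path(out_dir, "eae_profile.tsv"))
  } else {
    message("no ground-truth table supplied; EAE profile omitted")
  }
  write_config(out_dir, list(command = "scan", model = model_path,
                             vienna = vienna, truth = truth))
  invisible(out)
}
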