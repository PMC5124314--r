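#' Read a Vienna dot-bracket file
#'
#' Record format: a `">"` header line, the sequence line, then the structure
#' line, which may carry a trailing minimum-free-energy value in parentheses
#' (ignored), as printed by RNAfold.
#'
#' @param path File path.
#' @return A tibble `id`, `seq`, `db`.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no '>' records in ", path, call. = FALSE)
  if (any(diff(c(heads, length(lines) + 1L)) != 3L)) {
    stop("malformed Vienna file: each record needs a header, a sequence line ",
         "and a structure line", call. = FALSE)
  }
  id <- sub("^>\\s*", "", lines[heads])
  id <- sub("\\s.*$", "", id)
  seq <- toupper(trimws(lines[heads + 1L]))
  seq <- gsub("T", "U", seq, fixed = TRUE)
  db <- trimws(lines[heads + 2L])
  db <- sub("\\s*\\([-+0-9.\\s]*\\)\\s*$", "", db)  # strip trailing MFE
  bad <- nchar(seq) != nchar(db)
  if (any(bad)) {
    stop("sequence/structure length mismatch for: ",
         paste(id[bad], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = id, seq = seq, db = db)
}

#' Write a Vienna dot-bracket file
#'
#' @param tbl A tibble with `id`, `seq`, `db` columns.
#' @param path File path.
#' @export
write_vienna <- function(tbl, path) {
  writeLines(paste0(">", tbl$id, "\n", tbl$seq, "\n", tbl$db), path)
  invisible(path)
}

#' Read bare sequences from a FASTA file
#'
#' @param path File path.
#' @return A tibble `id`, `seq` (RNA alphabet, T read as U).
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    id <- sub("\\s.*$", "", names(set))
    seq <- toupper(as.character(set))
  } else {
    lines <- readLines(path)
    heads <- grep("^>", lines)
    id <- sub("\\s.*$", "", sub("^>\\s*", "", lines[heads]))
    bounds <- c(heads, length(lines) + 1L)
    seq <- vapply(seq_along(heads), function(i) {
      paste(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = "")
    }, character(1))
    seq <- toupper(seq)
  }
  tibble::tibble(id = unname(id), seq = gsub("T", "U", unname(seq), fixed = TRUE))
}

#' Read a mature-arm annotation table
#'
#' Tab-separated with a header; columns `id`, `mature5p_start`,
#' `mature5p_end`, `mature3p_start`, `mature3p_end` (1-based inclusive;
#' empty cells mark an absent arm).
#'
#' @param path File path.
#' @return A tibble with those columns.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    mature5p_start = readr::col_integer(),
    mature5p_end = readr::col_integer(),
    mature3p_start = readr::col_integer(),
    mature3p_end = readr::col_integer()
  ))
  missing <- setdiff(c("id", "mature5p_start", "mature5p_end",
                       "mature3p_start", "mature3p_end"), names(ann))
  if (length(missing) > 0L) {
    stop("annotation file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ann
}

#' Assemble precursors from a Vienna file and an annotation table
#'
#' Joins sequence/structure records to mature-arm coordinates by `id`;
#' ids present in one file but not the other are an error.
#'
#' @param vienna Path to a Vienna dot-bracket file.
#' @param annotation Path to an annotation TSV (see [read_annotation()]).
#' @return A precursors tibble.
#' @export
load_precursors <- function(vienna, annotation) {
  vtab <- read_vienna(vienna)
  ann <- read_annotation(annotation)
  orphans <- c(setdiff(vtab$id, ann$id), setdiff(ann$id, vtab$id))
  if (length(orphans) > 0L) {
    stop("ids not shared by structure and annotation files: ",
         paste(unique(orphans), collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::inner_join(vtab, ann, by = "id")
  precursors(joined$id, joined$seq, joined$db,
             m5_start = joined$mature5p_start, m5_end = joined$mature5p_end,
             m3_start = joined$mature3p_start, m3_end = joined$mature3p_end)
}

#' Write a labeled-window table for inspection
#'
#' @param windows A windows tibble from [make_windows()].
#' @param path File path.
#' @export
write_windows_tsv <- function(windows, path) {
  readr::write_tsv(
    windows[, c("id", "arm", "label", "center", "arm_tokens", "comp_tokens")],
    path
  )
  invisible(path)
}

#' Write encoded features in sparse SVM-light / libSVM format
#'
#' One line per window: the label (+1/-1) followed by `index:value` pairs of
#' the non-zero features, indices 1-based.
#'
#' @param features A `cleav_features` object from [encode_windows()].
#' @param path File path.
#' @export
write_svmlight <- function(features, path) {
  lines <- vapply(seq_len(nrow(features$x)), function(i) {
    nz <- which(features$x[i, ] != 0)
    paste(c(sprintf("%+d", features$y[i]),
            sprintf("%d:%g", nz, features$x[i, nz])), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write encoded features as a dense TSV
#'
#' @inheritParams write_svmlight
#' @export
write_features_tsv <- function(features, path) {
  mat <- as.data.frame(features$x)
  names(mat) <- paste0("f", seq_len(ncol(mat)))
  readr::write_tsv(dplyr::bind_cols(features$meta, mat), path)
  invisible(path)
}

model_format_version <- 1L

#' Serialize / restore a fitted model
#'
#' The archive holds a versioned header, the full encoding scheme (name,
#' `w`, `k`, `M`), the kernel parameters and the fitted SVM, so test-time
#' encoding always reuses the training `M`.
#'
#' @param model A `cleav_model` or `cleav_model_set`.
#' @param path File path for the archive.
#' @return `write_model` returns the path invisibly; `read_model` the
#'   restored model object.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cleav_model") || inherits(model, "cleav_model_set"))
  saveRDS(list(format = "lbcleav-model", version = model_format_version,
               model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "lbcleav-model")) {
    stop("not an lbcleav model archive: ", path, call. = FALSE)
  }
  if (obj$version > model_format_version) {
    stop("model archive version ", obj$version, " is newer than supported (",
         model_format_version, ")", call. = FALSE)
  }
  obj$model
}
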