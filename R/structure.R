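#' Parse a dot-bracket secondary structure into a base-pair map
#'
#' Builds the per-position partner table of a nested (pseudoknot-free) RNA
#' secondary structure written in Vienna dot-bracket notation, as produced by
#' MFE folding programs such as RNAfold. `'('` opens a base pair, `')'`
#' closes the most recent open one, `'.'` marks an unpaired position.
#'
#' @param structure A single dot-bracket string containing only `.`, `(`, `)`.
#' @return An object of class `pairmap`: a list with elements `length`
#'   (number of positions) and `partner` (integer vector, 1-based partner
#'   index or `NA` for unpaired positions).
#' @examples
#' pm <- parse_dotbracket("((..((....))..))")
#' pm$partner[1:2]   # 16, 15
#' @export
parse_dotbracket <- function(structure) {
  stopifnot(is.character(structure), length(structure) == 1L, !is.na(structure))
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  n <- length(chars)
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad) > 0L) {
    stop("illegal character '", chars[bad[1]], "' at position ", bad[1],
         " of dot-bracket string", call. = FALSE)
  }
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) {
        stop("unbalanced ')' at position ", i, call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack) > 0L) {
    stop("unbalanced '(' at position ", stack[length(stack)], call. = FALSE)
  }
  structure(list(length = n, partner = partner), class = "pairmap")
}

#' Render a pair map back to dot-bracket notation
#'
#' @param pairmap A `pairmap` from [parse_dotbracket()].
#' @return A dot-bracket string.
#' @export
render_dotbracket <- function(pairmap) {
  p <- pairmap$partner
  out <- rep(".", pairmap$length)
  out[!is.na(p) & p > seq_along(p)] <- "("
  out[!is.na(p) & p < seq_along(p)] <- ")"
  paste(out, collapse = "")
}

#' @export
print.pairmap <- function(x, ...) {
  cat("<pairmap> ", x$length, " nt, ", sum(!is.na(x$partner)) / 2,
      " base pairs\n", render_dotbracket(x), "\n", sep = "")
  invisible(x)
}

#' Annotate loop/bulge runs of a secondary structure
#'
#' A loop/bulge is a maximal run of consecutive unpaired positions on one
#' strand (contiguity in sequence coordinates); the terminal hairpin loop
#' counts like any bulge. Every unpaired position is assigned the length
#' `l` of the run that contains it; paired positions get 0.
#'
#' @param pairmap A `pairmap` from [parse_dotbracket()].
#' @return A tibble with one row per position: `pos`, `paired` (logical),
#'   `run_length` (integer, 0 for paired positions) and `run_id` (integer id
#'   of the maximal unpaired run, `NA` for paired positions).
#' @examples
#' annotate_loops(parse_dotbracket("((..((....))..))"))
#' @export
annotate_loops <- function(pairmap) {
  unpaired <- is.na(pairmap$partner)
  r <- rle(unpaired)
  run_length <- rep(ifelse(r$values, r$lengths, 0L), r$lengths)
  ids <- ifelse(r$values, cumsum(r$values), NA_integer_)
  run_id <- rep(ids, r$lengths)
  tibble::tibble(
    pos = seq_len(pairmap$length),
    paired = !unpaired,
    run_length = as.integer(run_length),
    run_id = run_id
  )
}

#' Locate the apex (terminal loop) of a hairpin and label its arms
#'
#' The apex is the unpaired run enclosed by the innermost base pair — the
#' pair with no other pair strictly inside it. Positions 5' of the apex are
#' tagged `"5p"`, positions 3' of it `"3p"`. If the structure contains
#' several hairpins (a multiloop), the innermost pair whose midpoint is
#' closest to the sequence midpoint is used, ties going to the 5'-most.
#'
#' @param pairmap A `pairmap` from [parse_dotbracket()].
#' @return A list with elements `apex_start`, `apex_end` (1-based inclusive
#'   range of the terminal loop) and `side` (character vector per position,
#'   one of `"5p"`, `"apex"`, `"3p"`).
#' @export
find_apex <- function(pairmap) {
  p <- pairmap$partner
  n <- pairmap$length
  opens <- which(!is.na(p) & p > seq_len(n))
  if (length(opens) == 0L) stop("no hairpin: structure contains no base pairs", call. = FALSE)
  # innermost pairs: no paired position strictly between i and partner[i]
  paired_pos <- !is.na(p)
  cum_paired <- cumsum(paired_pos)
  inner <- opens[vapply(opens, function(i) {
    j <- p[i]
    j > i + 1L && (cum_paired[j - 1L] - cum_paired[i]) == 0L
  }, logical(1))]
  if (length(inner) == 0L) {
    stop("no hairpin: no innermost pair encloses an unpaired loop", call. = FALSE)
  }
  mid <- (n + 1) / 2
  centers <- (inner + p[inner]) / 2
  best <- inner[order(abs(centers - mid), inner)][1]
  apex_start <- best + 1L
  apex_end <- p[best] - 1L
  side <- rep("apex", n)
  side[seq_len(n) < apex_start] <- "5p"
  side[seq_len(n) > apex_end] <- "3p"
  list(apex_start = apex_start, apex_end = apex_end, side = side)
}

#' Resolve the complementary-strand segment of a window
#'
#' For a window of `w` consecutive positions on one arm of a hairpin, returns
#' the `w` opposite-strand positions that face it: partners of the paired
#' window positions, plus any unpaired opposite-strand positions lying in the
#' span between the outermost partners, walked in window orientation. When
#' bulges make the facing span shorter or longer than `w`, the segment is
#' padded with `NA` gap placeholders, or trimmed, at the apex-distal end.
#'
#' @param window_start First (5'-most) position of the window.
#' @param w Window width in nucleotides.
#' @param pairmap A `pairmap` from [parse_dotbracket()].
#' @param apex Result of [find_apex()] for the same structure; computed when
#'   omitted.
#' @return Integer vector of length `w`: opposite-strand positions aligned to
#'   the window positions, `NA` marking gap placeholders.
#' @export
complementary_segment <- function(window_start, w, pairmap, apex = NULL) {
  if (is.null(apex)) apex <- find_apex(pairmap)
  win <- window_start:(window_start + w - 1L)
  if (win[1] < 1L || win[w] > pairmap$length) {
    stop("window [", win[1], ", ", win[w], "] out of bounds", call. = FALSE)
  }
  partners <- pairmap$partner[win]
  if (all(is.na(partners))) stop("no anchor pair in window", call. = FALSE)
  span <- seq(max(partners, na.rm = TRUE), min(partners, na.rm = TRUE), by = -1L)
  # drop opposite-strand positions that are themselves inside the window
  # (possible only when a scan window straddles the apex)
  span <- span[!span %in% win]
  # arm of the window decides which end is apex-distal: for a 5p window the
  # first position is farthest from the apex, for a 3p window the last one is.
  on_5p <- win[1] < apex$apex_start
  if (length(span) < w) {
    gaps <- rep(NA_integer_, w - length(span))
    span <- if (on_5p) c(gaps, span) else c(span, gaps)
  } else if (length(span) > w) {
    drop <- length(span) - w
    span <- if (on_5p) span[-seq_len(drop)] else span[seq_len(w)]
  }
  span
}

#' Maximum loop/bulge length of a set of structures
#'
#' `M`, the largest unpaired-run length observed across a dataset, fixes the
#' per-token dimension of the loop-length encoding.
#'
#' @param structures Character vector of dot-bracket strings, or a list of
#'   `pairmap` objects, or a precursors tibble with a `db` column.
#' @return Integer `M >= 0`.
#' @export
max_loop_length <- function(structures) {
  if (is.data.frame(structures)) structures <- structures$db
  if (length(structures) == 0L) stop("empty collection of structures", call. = FALSE)
  maxima <- vapply(structures, function(s) {
    pm <- if (inherits(s, "pairmap")) s else parse_dotbracket(s)
    max(annotate_loops(pm)$run_length)
  }, numeric(1), USE.NAMES = FALSE)
  as.integer(max(maxima))
}
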