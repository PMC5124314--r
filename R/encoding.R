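#' Define a binary encoding scheme for window tokens
#'
#' Four per-token binary patterns are supported:
#' \describe{
#'   \item{`"seq"`}{plain nucleotide one-hot, 4 dims per token; uses the
#'     arm-side window only (full vector `4w`).}
#'   \item{`"struct"`}{nucleotide one-hot with loop tokens mapped to the
#'     all-zero vector, 4 dims; arm + complementary tokens (`8w`).}
#'   \item{`"extended"`}{5-dim one-hot over A, U, C, G, L — a loop token is
#'     the fifth symbol regardless of its length (`10w`).}
#'   \item{`"lbsize"`}{length-aware pattern of dimension `M + k + 3`:
#'     nucleotides are one-hot in the first four slots, and a loop token of
#'     length `l` is written as `k` ones occupying slots `(4 + l)` through
#'     `(k + 3 + l)` (1-based), so that two loop tokens of lengths `l1`, `l2`
#'     have inner product `max(k - |l1 - l2|, 0)` (full vector
#'     `2w(M + k + 3)`).}
#' }
#' `M` is the maximum loop/bulge length of the training dataset; it is fixed
#' at fit time and reused when encoding test data (longer loops are clipped).
#'
#' @param name One of `"seq"`, `"struct"`, `"extended"`, `"lbsize"`.
#' @param w Even window width.
#' @param k Number of ones used for a loop token (lbsize only); larger `k`
#'   makes kernel similarity decay more slowly with `|l1 - l2|`.
#' @param M Maximum loop length (lbsize only). Leave `NULL` to have it
#'   resolved from the training windows at fit time.
#' @return An `encoding_scheme` object.
#' @export
encoding_scheme <- function(name = c("lbsize", "seq", "struct", "extended"),
                            w, k = 3L, M = NULL) {
  name <- match.arg(name)
  if (w %% 2L != 0L || w < 2L) stop("window size must be a positive even number", call. = FALSE)
  if (name == "lbsize") {
    if (k < 1L) stop("k must be a positive integer", call. = FALSE)
    if (!is.null(M) && M < 0L) stop("M must be >= 0", call. = FALSE)
  }
  structure(
    list(name = name, w = as.integer(w),
         k = if (name == "lbsize") as.integer(k) else NA_integer_,
         M = if (name == "lbsize" && !is.null(M)) as.integer(M) else NULL),
    class = "encoding_scheme"
  )
}

#' @export
print.encoding_scheme <- function(x, ...) {
  cat("<encoding_scheme> ", x$name, ", w = ", x$w, sep = "")
  if (x$name == "lbsize") {
    cat(", k = ", x$k, ", M = ", if (is.null(x$M)) "<unresolved>" else x$M, sep = "")
  }
  cat(", vector length = ",
      if (is.null(x$M) && x$name == "lbsize") "2w(M+k+3), M pending"
      else scheme_length(x), "\n", sep = "")
  invisible(x)
}

# per-token dimension d
token_dim <- function(scheme) {
  switch(scheme$name,
    seq = 4L, struct = 4L, extended = 5L,
    lbsize = {
      if (is.null(scheme$M)) stop("lbsize scheme has unresolved M", call. = FALSE)
      scheme$M + scheme$k + 3L
    }
  )
}

# full feature-vector length: 4w (seq, arm side only) or 2*w*d otherwise
scheme_length <- function(scheme) {
  d <- token_dim(scheme)
  if (scheme$name == "seq") scheme$w * d else 2L * scheme$w * d
}

#' Resolve the `M` of an lbsize scheme from training windows
#'
#' Sets `M` to the largest loop length appearing among the arm and
#' complementary tokens of `windows`. Schemes other than lbsize, or schemes
#' whose `M` is already set, are returned unchanged.
#'
#' @param scheme An `encoding_scheme`.
#' @param windows A windows tibble from [make_windows()].
#' @return The scheme with `M` fixed.
#' @export
resolve_scheme <- function(scheme, windows) {
  if (scheme$name != "lbsize" || !is.null(scheme$M)) return(scheme)
  ls <- c(unlist(windows$arm_l), unlist(windows$comp_l))
  scheme$M <- max(0L, ls[!is.na(ls)])
  scheme
}

#' Encode a single token under a scheme
#'
#' @param nt Nucleotide letter (A/U/C/G), or `NA` for a gap placeholder.
#' @param l Loop run length at the position (0 when base-paired, `NA` for a
#'   gap).
#' @param scheme An `encoding_scheme` with `M` resolved if lbsize.
#' @return Binary numeric vector of the scheme's per-token dimension.
#' @examples
#' encode_token("A", 0, encoding_scheme("seq", w = 6))
#' encode_token("G", 1, encoding_scheme("lbsize", w = 6, k = 3, M = 5))
#' @export
encode_token <- function(nt, l, scheme) {
  d <- token_dim(scheme)
  v <- numeric(d)
  if (is.na(nt) && (is.na(l) || l == 0L)) return(v)  # gap placeholder
  is_loop <- !is.na(l) && l > 0L
  if (is_loop && scheme$name != "seq") {
    if (scheme$name == "struct") return(v)           # L -> [0,0,0,0]
    if (scheme$name == "extended") { v[5] <- 1; return(v) }
    lc <- l
    if (lc > scheme$M) {
      warning("loop length ", l, " exceeds scheme M = ", scheme$M,
              "; clipped", call. = FALSE)
      lc <- scheme$M
    }
    v[(4L + lc):(scheme$k + 3L + lc)] <- 1
    return(v)
  }
  slot <- match(nt, c("A", "U", "C", "G"))
  if (is.na(slot)) stop("invalid nucleotide token '", nt, "'", call. = FALSE)
  v[slot] <- 1
  v
}

# encode a token list (nt, l vectors) into one flat numeric vector
encode_tokens <- function(nt, l, scheme) {
  as.numeric(vapply(seq_along(nt),
                    function(i) encode_token(nt[i], l[i], scheme),
                    numeric(token_dim(scheme))))
}

#' Encode labeled windows into a binary feature matrix
#'
#' Concatenates the per-token patterns of the arm-side tokens and (for the
#' structure-aware schemes) the complementary-strand tokens. The `"seq"`
#' scheme uses arm nucleotides only and ignores structure entirely. Loop
#' lengths larger than the scheme's `M` are clipped to `M` with one warning.
#'
#' @param windows A windows tibble from [make_windows()].
#' @param scheme An `encoding_scheme`; an unresolved lbsize `M` is computed
#'   from `windows` (see [resolve_scheme()]).
#' @return A `cleav_features` object: list with the feature `matrix` `x`
#'   (one row per window), the label vector `y` (+1/-1), the window
#'   metadata tibble `meta` and the resolved `scheme`.
#' @export
encode_windows <- function(windows, scheme) {
  scheme <- resolve_scheme(scheme, windows)
  stopifnot(all(lengths(windows$arm_nt) == scheme$w))
  n <- nrow(windows)
  clipped <- FALSE
  x <- withCallingHandlers(
    {
      rows <- purrr::map(seq_len(n), function(i) {
        if (scheme$name == "seq") {
          encode_tokens(windows$arm_nt[[i]], windows$arm_l[[i]], scheme)
        } else {
          c(encode_tokens(windows$arm_nt[[i]], windows$arm_l[[i]], scheme),
            encode_tokens(windows$comp_nt[[i]], windows$comp_l[[i]], scheme))
        }
      })
      do.call(rbind, rows)
    },
    warning = function(w) {
      if (grepl("clipped", conditionMessage(w))) {
        clipped <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (clipped) {
    warning("some loop lengths exceeded scheme M = ", scheme$M,
            " and were clipped", call. = FALSE)
  }
  if (is.null(x)) x <- matrix(numeric(0), nrow = 0L, ncol = scheme_length(scheme))
  structure(
    list(x = x, y = windows$label,
         meta = windows[, c("id", "arm", "label", "center")],
         scheme = scheme),
    class = "cleav_features"
  )
}

#' @export
print.cleav_features <- function(x, ...) {
  cat("<cleav_features> ", nrow(x$x), " windows x ", ncol(x$x),
      " binary features (", x$scheme$name, ")\n", sep = "")
  invisible(x)
}

#' Closed-form inner product of two loop tokens under the lbsize pattern
#'
#' Two loop tokens of lengths `l1` and `l2`, each written as `k` ones at an
#' offset set by its length, share `max(k - |l1 - l2|, 0)` overlapping ones.
#'
#' @param l1,l2 Loop lengths (positive integers); vectorized.
#' @param k Number of ones per loop token.
#' @return Integer inner product.
#' @export
loop_dot <- function(l1, l2, k) {
  stopifnot(all(l1 >= 1), all(l2 >= 1), k >= 1)
  pmax(k - abs(l1 - l2), 0)
}

#' Closed-form squared distance of two loop tokens under the lbsize pattern
#'
#' Since each loop token holds exactly `k` ones,
#' `||x1 - x2||^2 = 2k - 2 max(k - |l1 - l2|, 0) = 2 min(|l1 - l2|, k)`:
#' the RBF kernel between two loop tokens is
#' `exp(-2 * gamma * min(|l1 - l2|, k))`, decaying with the length
#' difference and saturating once the blocks of ones no longer overlap.
#'
#' @inheritParams loop_dot
#' @return Integer squared Euclidean distance.
#' @export
loop_sqdist <- function(l1, l2, k) {
  stopifnot(all(l1 >= 1), all(l2 >= 1), k >= 1)
  2 * pmin(abs(l1 - l2), k)
}
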