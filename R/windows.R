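#' Build a precursors tibble
#'
#' The canonical container of this package: one row per pre-miRNA hairpin,
#' with its RNA sequence, predicted secondary structure and the 1-based
#' inclusive coordinates of the annotated mature arms (either may be absent).
#'
#' @param id Character vector of precursor ids.
#' @param seq RNA sequences (T is accepted and read as U; case is ignored).
#' @param db Dot-bracket structures, same lengths as `seq`.
#' @param m5_start,m5_end,m3_start,m3_end Mature-arm coordinates (1-based
#'   inclusive), `NA` for an absent arm.
#' @return A tibble with those columns, validated.
#' @export
precursors <- function(id, seq, db,
                       m5_start = NA_integer_, m5_end = NA_integer_,
                       m3_start = NA_integer_, m3_end = NA_integer_) {
  tbl <- tibble::tibble(
    id = as.character(id),
    seq = toupper(as.character(seq)),
    db = as.character(db),
    m5_start = as.integer(m5_start), m5_end = as.integer(m5_end),
    m3_start = as.integer(m3_start), m3_end = as.integer(m3_end)
  )
  tbl$seq <- gsub("T", "U", tbl$seq, fixed = TRUE)
  bad_len <- nchar(tbl$seq) != nchar(tbl$db)
  if (any(bad_len)) {
    stop("sequence/structure length mismatch for id(s): ",
         paste(tbl$id[bad_len], collapse = ", "), call. = FALSE)
  }
  both <- !is.na(tbl$m5_end) & !is.na(tbl$m3_start)
  if (any(both & tbl$m5_end >= tbl$m3_start)) {
    stop("mature 5p arm must end before the 3p arm starts", call. = FALSE)
  }
  tbl
}

#' Locate Dicer cleavage sites from mature-arm coordinates
#'
#' Cleavage sites are inter-nucleotide indices: site `s` is the cut between
#' positions `s` and `s + 1`. The 5p-arm site (CD-5p) falls just after the
#' last nucleotide of the 5p mature product; the 3p-arm site (CD-3p) just
#' before the first nucleotide of the 3p mature product.
#'
#' @param precursors A precursors tibble (see [precursors()]).
#' @return A tibble `id`, `cd5p`, `cd3p` (`NA` where the arm is absent).
#' @export
locate_cleavage_sites <- function(precursors) {
  if (all(is.na(precursors$m5_end)) && all(is.na(precursors$m3_start))) {
    stop("no mature-arm coordinates present", call. = FALSE)
  }
  tibble::tibble(
    id = precursors$id,
    cd5p = precursors$m5_end,
    cd3p = precursors$m3_start - 1L
  )
}

# token rendering used in window tables and messages: "A", "L3" or "-"
render_tokens <- function(nt, l) {
  out <- ifelse(is.na(nt), "-", ifelse(!is.na(l) & l > 0L, paste0("L", l), nt))
  paste(out, collapse = " ")
}

#' Extract the tokens of one window
#'
#' A window of even width `w` centered on inter-nucleotide site `s` covers
#' positions `s - w/2 + 1` through `s + w/2`. Each position is tokenized as
#' its nucleotide when base-paired, or as a loop symbol `L_l` (where `l` is
#' the length of its unpaired run) otherwise.
#'
#' @param site Inter-nucleotide index (cut after position `site`).
#' @param w Even window width.
#' @param seq RNA sequence (single string).
#' @param loops Loop annotation from [annotate_loops()].
#' @return A list with `pos`, `nt`, `l` (vectors of length `w`).
#' @export
extract_window <- function(site, w, seq, loops) {
  if (w %% 2L != 0L || w < 2L) stop("window size must be a positive even number", call. = FALSE)
  pos <- (site - w %/% 2L + 1L):(site + w %/% 2L)
  n <- nchar(seq)
  if (pos[1] < 1L || pos[w] > n) {
    stop("window truncated: positions [", pos[1], ", ", pos[w],
         "] exceed sequence of length ", n, call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  list(pos = pos, nt = chars[pos], l = loops$run_length[pos])
}

# Tokenize an opposite-strand segment: NA positions become gap placeholders.
comp_tokens <- function(segment, seq, loops) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  list(
    pos = segment,
    nt = ifelse(is.na(segment), NA_character_, chars[ifelse(is.na(segment), 1L, segment)]),
    l = ifelse(is.na(segment), NA_integer_, loops$run_length[ifelse(is.na(segment), 1L, segment)])
  )
}

#' Build labeled positive/negative windows for every precursor
#'
#' For each arm with an annotated cleavage site, emits one positive window
#' centered exactly on the site and one negative window centered `offset`
#' nucleotides away (by default 6 nt toward the apex, i.e. into the region
#' removed by Dicer). Each window carries both its own-arm tokens and the
#' tokens of the complementary segment on the opposite strand. Windows that
#' would run off the sequence, leave their arm, or face no base pair are
#' skipped with a warning.
#'
#' @param precursors A precursors tibble.
#' @param w Even window width (the paper's sweep uses 8, 10, 12, 14).
#' @param offset Distance in nt between positive and negative centers
#'   (default 6).
#' @param direction `"toward-apex"` (default) or `"toward-terminus"`: where
#'   the negative center lies relative to the true site.
#' @return A tibble with one row per window: `id`, `arm`, `label` (+1/-1),
#'   `center`, list-columns `arm_nt`, `arm_l`, `comp_nt`, `comp_l`, and
#'   rendered `arm_tokens` / `comp_tokens` strings.
#' @examples
#' pre <- precursors("px",
#'   seq = paste0("GGGGCAGUAAGUUCGA", "AAAC", "UCGAACUUACUGCCCC"),
#'   db  = paste0(strrep("(", 16), "....", strrep(")", 16)),
#'   m5_start = 1, m5_end = 7, m3_start = 31, m3_end = 36)
#' make_windows(pre, w = 6)
#' @export
make_windows <- function(precursors, w, offset = 6L,
                         direction = c("toward-apex", "toward-terminus")) {
  direction <- match.arg(direction)
  if (w %% 2L != 0L || w < 2L) stop("window size must be a positive even number", call. = FALSE)
  sites <- locate_cleavage_sites(precursors)
  rows <- purrr::pmap(
    list(precursors$id, precursors$seq, precursors$db, sites$cd5p, sites$cd3p),
    function(id, seq, db, cd5p, cd3p) {
      pm <- parse_dotbracket(db)
      loops <- annotate_loops(pm)
      apex <- find_apex(pm)
      sgn <- if (direction == "toward-apex") 1L else -1L
      specs <- list()
      if (!is.na(cd5p)) {
        specs <- c(specs, list(
          list(arm = "5p", label = 1L, center = cd5p),
          list(arm = "5p", label = -1L, center = cd5p + sgn * offset)
        ))
      }
      if (!is.na(cd3p)) {
        specs <- c(specs, list(
          list(arm = "3p", label = 1L, center = cd3p),
          list(arm = "3p", label = -1L, center = cd3p - sgn * offset)
        ))
      }
      purrr::map(specs, function(sp) {
        window_record(id, sp$arm, sp$label, sp$center, w, seq, pm, loops, apex)
      })
    }
  )
  rows <- purrr::compact(purrr::flatten(rows))
  if (length(rows) == 0L) {
    return(tibble::tibble(
      id = character(), arm = character(), label = integer(), center = integer(),
      arm_nt = list(), arm_l = list(), comp_nt = list(), comp_l = list(),
      arm_tokens = character(), comp_tokens = character()
    ))
  }
  dplyr::bind_rows(rows)
}

# one labeled window, or NULL (with a warning) when it cannot be formed
window_record <- function(id, arm, label, center, w, seq, pm, loops, apex) {
  win <- tryCatch(extract_window(center, w, seq, loops), error = function(e) e)
  if (inherits(win, "error")) {
    warning("skipping ", arm, " window of ", id, " at site ", center, ": ",
            conditionMessage(win), call. = FALSE)
    return(NULL)
  }
  sides <- apex$side[win$pos]
  if (!all(sides == arm)) {
    warning("skipping ", arm, " window of ", id, " at site ", center,
            ": window leaves the ", arm, " arm", call. = FALSE)
    return(NULL)
  }
  seg <- tryCatch(complementary_segment(win$pos[1], w, pm, apex),
                  error = function(e) e)
  if (inherits(seg, "error")) {
    warning("skipping ", arm, " window of ", id, " at site ", center, ": ",
            conditionMessage(seg), call. = FALSE)
    return(NULL)
  }
  cmp <- comp_tokens(seg, seq, loops)
  tibble::tibble(
    id = id, arm = arm, label = label, center = as.integer(center),
    arm_nt = list(win$nt), arm_l = list(win$l),
    comp_nt = list(cmp$nt), comp_l = list(cmp$l),
    arm_tokens = render_tokens(win$nt, win$l),
    comp_tokens = render_tokens(cmp$nt, cmp$l)
  )
}
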