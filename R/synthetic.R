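#' Parameters for the synthetic hairpin generator
#'
#' Describes a population of pre-miRNA-like stem-loops: a mostly base-paired
#' stem interrupted by unpaired bulges of controlled lengths, a terminal
#' (apex) loop, annotated mature arms on both strands, and an optional
#' planted cleavage cue. The cue is either a fixed 4-mer written into the
#' sequence flanking the cut (`"sequence-motif"`), a bulge of a signature
#' length at a fixed offset from the cut (`"loop-length"`), or both
#' (`"mixed"`). `signal_strength` is the per-arm probability that the cue is
#' planted; at 0 the windows carry no label-dependent information at all.
#'
#' @param n_precursors Number of hairpins to generate.
#' @param stem_range Range (min, max) of base-paired stem columns.
#' @param apex_range Range of terminal-loop lengths.
#' @param bulge_rate Per-construction-step probability of inserting a bulge.
#' @param bulge_len_max Largest background bulge length.
#' @param bulge_len_prob Probabilities over lengths `1:bulge_len_max`
#'   (default geometric, halving per extra nucleotide).
#' @param signal_mode One of `"loop-length"`, `"sequence-motif"`, `"mixed"`,
#'   `"none"`.
#' @param signal_strength Probability the cue is planted at a true site.
#' @param signature_length Loop length of the planted bulge.
#' @param signature_offset Offset of the planted bulge's last nucleotide
#'   relative to the cut (default -2: the run covers the three nucleotides
#'   ending at the cleavage site).
#' @param motif 4-mer written at the cut under the sequence-motif modes.
#' @param mature_range Range of mature-arm lengths.
#' @param wobble_rate Fraction of stem pairs drawn as G·U wobbles rather
#'   than Watson-Crick pairs.
#' @param seed Integer seed used by [generate_dataset()].
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_precursors = 100L,
                         stem_range = c(38L, 46L),
                         apex_range = c(4L, 8L),
                         bulge_rate = 0.08,
                         bulge_len_max = 4L,
                         bulge_len_prob = NULL,
                         signal_mode = c("loop-length", "sequence-motif",
                                         "mixed", "none"),
                         signal_strength = 0.9,
                         signature_length = 3L,
                         signature_offset = -2L,
                         motif = "GCAG",
                         mature_range = c(20L, 23L),
                         wobble_rate = 0.1,
                         seed = 1L) {
  signal_mode <- match.arg(signal_mode)
  if (is.null(bulge_len_prob)) {
    bulge_len_prob <- 0.5^seq_len(bulge_len_max)
  }
  bulge_len_prob <- bulge_len_prob / sum(bulge_len_prob)
  stopifnot(
    n_precursors >= 0L,
    length(stem_range) == 2L, stem_range[1] <= stem_range[2],
    length(apex_range) == 2L, apex_range[1] >= 1L, apex_range[1] <= apex_range[2],
    bulge_rate >= 0, bulge_rate <= 1,
    bulge_len_max >= 1L, length(bulge_len_prob) == bulge_len_max,
    signal_strength >= 0, signal_strength <= 1,
    signature_length >= 1L, nchar(motif) >= 1L,
    length(mature_range) == 2L, mature_range[1] <= mature_range[2],
    wobble_rate >= 0, wobble_rate <= 1
  )
  structure(
    list(n_precursors = as.integer(n_precursors),
         stem_range = as.integer(stem_range), apex_range = as.integer(apex_range),
         bulge_rate = bulge_rate, bulge_len_max = as.integer(bulge_len_max),
         bulge_len_prob = bulge_len_prob, signal_mode = signal_mode,
         signal_strength = signal_strength,
         signature_length = as.integer(signature_length),
         signature_offset = as.integer(signature_offset), motif = toupper(motif),
         mature_range = as.integer(mature_range), wobble_rate = wobble_rate,
         seed = as.integer(seed)),
    class = "synth_params"
  )
}

rna_complement <- c(A = "U", U = "A", C = "G", G = "C")

#' Generate one synthetic hairpin precursor
#'
#' Draws from the current RNG state (see [generate_dataset()] for seeded
#' batches). The stem is built column by column from the terminus toward the
#' apex; background bulges alternate between strands, and when a cue is
#' planted its bulge is placed so that its run ends `signature_offset`
#' nucleotides from the cut, never merging with a background bulge.
#'
#' @param params A `synth_params` list.
#' @param id Precursor id string.
#' @return A one-row precursors tibble with extra truth columns `cd5p`,
#'   `cd3p`, `signal5p`, `signal3p`.
#' @export
generate_precursor <- function(params, id = "synth-1") {
  p <- params
  n_pairs <- sample(p$stem_range[1]:p$stem_range[2], 1L)
  apex_len <- sample(p$apex_range[1]:p$apex_range[2], 1L)
  mat5 <- sample(p$mature_range[1]:p$mature_range[2], 1L)
  mat3 <- sample(p$mature_range[1]:p$mature_range[2], 1L)
  lead5 <- sample(0:2, 1L)
  lead3 <- sample(0:2, 1L)
  a <- lead5 + mat5                       # cd5p: cut after 5p position a
  b <- lead3 + mat3                       # cd3p: cut b nt before the 3' end
  plant5 <- stats::runif(1) < p$signal_strength
  plant3 <- stats::runif(1) < p$signal_strength
  loop_cue <- p$signal_mode %in% c("loop-length", "mixed")
  motif_cue <- p$signal_mode %in% c("sequence-motif", "mixed")
  sigL <- p$signature_length
  sig5_pending <- plant5 && loop_cue
  sig3_pending <- plant3 && loop_cue
  trig5 <- a + p$signature_offset - 1L    # p5 count at which the 5p cue starts
  trig3 <- b - sigL                       # n3 count at which the 3p cue starts
  if (sig5_pending && trig5 < 0L) stop("infeasible geometry: cue before 5' end", call. = FALSE)
  if (sig3_pending && trig3 < 0L) stop("infeasible geometry: cue before 3' end", call. = FALSE)

  seq5 <- character(0); db5 <- character(0)
  seq3 <- character(0); db3 <- character(0)    # from the 3' terminus inward
  p5 <- 0L; n3 <- 0L; pairs <- 0L
  sig5_planted <- FALSE; sig3_planted <- FALSE
  bulge_side <- "5p"
  last_was_bulge <- FALSE   # at least one pair between bulges, so run
                            # lengths follow the requested distribution
  emit_bulge <- function(side, len) {
    nts <- sample(names(rna_complement), len, replace = TRUE)
    if (side == "5p") {
      seq5 <<- c(seq5, nts); db5 <<- c(db5, rep(".", len)); p5 <<- p5 + len
    } else {
      seq3 <<- c(seq3, nts); db3 <<- c(db3, rep(".", len)); n3 <<- n3 + len
    }
  }
  while (pairs < n_pairs) {
    if (sig5_pending && p5 == trig5) {
      emit_bulge("5p", sigL); sig5_pending <- FALSE; sig5_planted <- TRUE
      last_was_bulge <- TRUE; next
    }
    if (sig3_pending && n3 == trig3) {
      emit_bulge("3p", sigL); sig3_pending <- FALSE; sig3_planted <- TRUE
      last_was_bulge <- TRUE; next
    }
    if (!last_was_bulge && stats::runif(1) < p$bulge_rate) {
      side <- bulge_side
      bulge_side <- if (bulge_side == "5p") "3p" else "5p"
      len <- sample.int(p$bulge_len_max, 1L, prob = p$bulge_len_prob)
      if (side == "5p") {
        if (sig5_pending && p5 < trig5) len <- min(len, trig5 - 1L - p5)
        if (sig5_planted && p5 == a) len <- 0L   # would merge with the cue
      } else {
        if (sig3_pending && n3 < trig3) len <- min(len, trig3 - 1L - n3)
        if (sig3_planted && n3 == b) len <- 0L
      }
      if (len >= 1L) { emit_bulge(side, len); last_was_bulge <- TRUE; next }
    }
    last_was_bulge <- FALSE
    b5 <- sample(names(rna_complement), 1L)
    b3 <- if (b5 %in% c("G", "U") && stats::runif(1) < p$wobble_rate) {
      if (b5 == "G") "U" else "G"                # G.U wobble pair
    } else rna_complement[[b5]]
    seq5 <- c(seq5, b5); db5 <- c(db5, "(")
    seq3 <- c(seq3, b3); db3 <- c(db3, ")")
    pairs <- pairs + 1L; p5 <- p5 + 1L; n3 <- n3 + 1L
  }
  if (a > p5 || b > n3) stop("infeasible geometry: mature arm longer than stem arm", call. = FALSE)
  apex_chars <- sample(names(rna_complement), apex_len, replace = TRUE)
  seq_chars <- c(seq5, apex_chars, rev(seq3))
  db_chars <- c(db5, rep(".", apex_len), rev(db3))
  len_total <- length(seq_chars)
  cd3p <- len_total - b

  if (motif_cue) {
    motif_chars <- strsplit(p$motif, "", fixed = TRUE)[[1]]
    mlen <- length(motif_chars)
    protected <- integer(0)
    if (plant3) protected <- c(protected, (cd3p + 1L):(cd3p + mlen))
    if (plant5) protected <- c(protected, (a - mlen + 1L):a)
    place <- function(from) {
      idx <- from:(from + mlen - 1L)
      seq_chars[idx] <<- motif_chars
    }
    if (plant3) place(cd3p + 1L)
    if (plant5) place(a - mlen + 1L)
    pm <- parse_dotbracket(paste(db_chars, collapse = ""))
    for (pos in protected) {
      q <- pm$partner[pos]
      if (!is.na(q) && !q %in% protected) {
        seq_chars[q] <- rna_complement[[seq_chars[pos]]]
      }
    }
  }

  tibble::tibble(
    id = id,
    seq = paste(seq_chars, collapse = ""),
    db = paste(db_chars, collapse = ""),
    m5_start = lead5 + 1L, m5_end = a,
    m3_start = cd3p + 1L, m3_end = cd3p + mat3,
    cd5p = a, cd3p = cd3p,
    signal5p = plant5, signal3p = plant3
  )
}

#' Generate a seeded synthetic dataset
#'
#' @param params A `synth_params` list; `params$seed` fixes the whole batch,
#'   so equal parameters give identical datasets.
#' @return A precursors tibble of `n_precursors` rows carrying the ground
#'   truth columns `cd5p`, `cd3p`, `signal5p`, `signal3p`.
#' @examples
#' ds <- generate_dataset(synth_params(n_precursors = 3, seed = 42))
#' ds$id
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  if (params$n_precursors == 0L) {
    return(withr::with_seed(params$seed,
                            generate_precursor(params, id = "void"))[0, ])
  }
  withr::with_seed(
    params$seed,
    dplyr::bind_rows(purrr::map(
      seq_len(params$n_precursors),
      ~ generate_precursor(params, id = sprintf("synth-%04d", .x))
    ))
  )
}

#' Write a synthetic dataset to disk
#'
#' Emits the same file dialects the loaders read, so synthetic and real data
#' flow through identical code paths: a FASTA file, a Vienna
#' sequence/structure file, the mature-arm annotation TSV, and a
#' ground-truth TSV with the true cleavage sites and planted-cue flags.
#'
#' @param dataset A tibble from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, "precursors.fa"),
    vienna = file.path(dir, "precursors.vienna"),
    annotation = file.path(dir, "annotation.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  writeLines(paste0(">", dataset$id, "\n", dataset$seq), paths$fasta)
  write_vienna(dataset, paths$vienna)
  readr::write_tsv(
    tibble::tibble(id = dataset$id,
                   mature5p_start = dataset$m5_start, mature5p_end = dataset$m5_end,
                   mature3p_start = dataset$m3_start, mature3p_end = dataset$m3_end),
    paths$annotation
  )
  readr::write_tsv(
    dataset[, c("id", "cd5p", "cd3p", "signal5p", "signal3p")],
    paths$truth
  )
  invisible(paths)
}

#' Worked-example fixture windows
#'
#' A pair of hand-checkable `w = 6` windows modeled on the hsa-miR-200c
#' precursor: a positive 5p-arm window whose letters UGGGUG contain two
#' single-nucleotide loops (positions 1 and 5 of the window), tokenizing to
#' `L1 G G G L1 G`, and a fully base-paired negative 3p-arm window CGUCAU
#' that encodes as six plain one-hots. Complementary tokens are gap
#' placeholders; the fixture exercises arm-side tokenization and encoding
#' (with `k = 3`, the per-arm lbsize vector has length `6(M + 6)`).
#'
#' @return A windows tibble with two rows, with attributes `w = 6` and
#'   `k = 3`.
#' @export
fixture_fig1 <- function() {
  gap_nt <- rep(NA_character_, 6L)
  gap_l <- rep(NA_integer_, 6L)
  out <- tibble::tibble(
    id = c("mir-200c-example", "mir-200c-example"),
    arm = c("5p", "3p"),
    label = c(1L, -1L),
    center = NA_integer_,
    arm_nt = list(c("U", "G", "G", "G", "U", "G"),
                  c("C", "G", "U", "C", "A", "U")),
    arm_l = list(c(1L, 0L, 0L, 0L, 1L, 0L), rep(0L, 6L)),
    comp_nt = list(gap_nt, gap_nt),
    comp_l = list(gap_l, gap_l),
    arm_tokens = c("L1 G G G L1 G", "C G U C A U"),
    comp_tokens = rep(paste(rep("-", 6L), collapse = " "), 2L)
  )
  attr(out, "w") <- 6L
  attr(out, "k") <- 3L
  out
}
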