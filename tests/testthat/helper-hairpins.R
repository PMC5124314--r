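# Fixtures built in code: small hairpins with hand-checkable structure.

# perfect stem-loop: n_pairs stem columns, apex unpaired nucleotides
perfect_hairpin <- function(n_pairs = 16, apex = 4, seed = 1) {
  comp <- c(A = "U", U = "A", C = "G", G = "C")
  arm5 <- withr::with_seed(seed, sample(names(comp), n_pairs, replace = TRUE))
  apex_nt <- withr::with_seed(seed + 1, sample(names(comp), apex, replace = TRUE))
  arm3 <- rev(unname(comp[arm5]))
  list(
    seq = paste(c(arm5, apex_nt, arm3), collapse = ""),
    db = paste0(strrep("(", n_pairs), strrep(".", apex), strrep(")", n_pairs))
  )
}

# stem with a single 1-nt bulge on the 5p strand between pair columns 5 and 6
# 5p: ((((( . (((((   apex ....   3p: ))))))))))   (25 nt total)
bulge5_hairpin <- function() {
  list(
    seq = paste0(strrep("A", 5), "C", strrep("A", 5), "GGGG", strrep("U", 10)),
    db = paste0("(((((", ".", "(((((", "....", strrep(")", 10))
  )
}

# stem with a single 1-nt bulge on the 3p strand between pair columns 5 and 6
# 5p: ((((((((((   apex ....   3p: ))))) . )))))   (25 nt total)
bulge3_hairpin <- function() {
  list(
    seq = paste0(strrep("A", 10), "GGGG", strrep("U", 5), "C", strrep("U", 5)),
    db = paste0(strrep("(", 10), "....", ")))))", ".", ")))))")
  )
}

# brute-force loop run length: count consecutive unpaired neighbors around i
bf_run_length <- function(db) {
  unpaired <- strsplit(db, "")[[1]] == "."
  n <- length(unpaired)
  vapply(seq_len(n), function(i) {
    if (!unpaired[i]) return(0L)
    len <- 1L
    j <- i - 1L
    while (j >= 1L && unpaired[j]) { len <- len + 1L; j <- j - 1L }
    j <- i + 1L
    while (j <= n && unpaired[j]) { len <- len + 1L; j <- j + 1L }
    len
  }, integer(1))
}

# hand-built windows tibble for feature-level model tests
manual_windows <- function(arm_nt, labels, ids = NULL, arm = "5p") {
  w <- length(arm_nt[[1]])
  n <- length(arm_nt)
  tibble::tibble(
    id = if (is.null(ids)) sprintf("m%02d", seq_len(n)) else ids,
    arm = arm,
    label = as.integer(labels),
    center = NA_integer_,
    arm_nt = arm_nt,
    arm_l = purrr::map(arm_nt, ~ rep(0L, length(.x))),
    comp_nt = purrr::map(arm_nt, ~ rep(NA_character_, length(.x))),
    comp_l = purrr::map(arm_nt, ~ rep(NA_integer_, length(.x))),
    arm_tokens = purrr::map_chr(arm_nt, paste, collapse = " "),
    comp_tokens = purrr::map_chr(arm_nt, ~ paste(rep("-", length(.x)), collapse = " "))
  )
}

# join predicted sites to synthetic ground truth and return per-arm EAEs
site_errors <- function(pred, dataset) {
  truth <- dplyr::bind_rows(
    tibble::tibble(id = dataset$id, arm = "5p", true_site = dataset$cd5p),
    tibble::tibble(id = dataset$id, arm = "3p", true_site = dataset$cd3p)
  )
  j <- dplyr::inner_join(pred, truth, by = c("id", "arm"))
  end_absolute_error(j$site, j$true_site)
}

# widen the worked-example fixture to window size w (token content recycled);
# strip_loops replaces loop tokens by plain nucleotides so that M = 0 schemes
# apply without clipping
pad_fixture <- function(fx, w, strip_loops = FALSE) {
  fx$arm_nt <- purrr::map(fx$arm_nt, ~ rep_len(.x, w))
  fx$arm_l <- purrr::map(fx$arm_l, ~ rep_len(if (strip_loops) 0L * .x else .x, w))
  fx$comp_nt <- purrr::map(fx$comp_nt, ~ rep(NA_character_, w))
  fx$comp_l <- purrr::map(fx$comp_l, ~ rep(NA_integer_, w))
  fx$arm_tokens <- purrr::map2_chr(fx$arm_nt, fx$arm_l, render_tokens)
  fx$comp_tokens <- paste(rep("-", w), collapse = " ")
  fx
}
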