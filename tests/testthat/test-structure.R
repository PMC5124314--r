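test_that("parse_dotbracket recovers forced pairings", {
  pm <- parse_dotbracket("((..))")
  expect_equal(pm$partner, c(6L, 5L, NA, NA, 2L, 1L))

  pm <- parse_dotbracket("......")
  expect_true(all(is.na(pm$partner)))
  expect_equal(pm$length, 6L)

  # frozen from a stack walk done by hand: pairs 1-16, 2-15, 5-12, 6-11
  pm <- parse_dotbracket("((..((....))..))")
  expect_equal(pm$partner[c(1, 2, 5, 6)], c(16L, 15L, 12L, 11L))
  expect_true(all(is.na(pm$partner[c(3, 4, 7:10, 13, 14)])))
})

test_that("pair maps are symmetric and self-pairing-free", {
  for (db in c("((..))", "((..((....))..))", "(((...)))", "(.)((...))")) {
    p <- parse_dotbracket(db)$partner
    paired <- which(!is.na(p))
    expect_equal(p[p[paired]], paired)
    expect_false(any(p[paired] == paired))
  }
})

test_that("parse errors name the offending position", {
  expect_error(parse_dotbracket("((..)"), "position 1")
  expect_error(parse_dotbracket("(..))"), "position 5")
  expect_error(parse_dotbracket("((.x))"), "illegal character 'x' at position 4")
})

test_that("parse and render are mutually inverse on valid strings", {
  dbs <- c("((..))", "......", "((..((....))..))",
           generate_dataset(synth_params(n_precursors = 10, seed = 5))$db)
  for (db in dbs) {
    expect_identical(render_dotbracket(parse_dotbracket(db)), db)
  }
})

test_that("annotate_loops matches the run-length scan oracle", {
  loops <- annotate_loops(parse_dotbracket("((..((....))..))"))
  expect_equal(loops$run_length,
               c(0, 0, 2, 2, 0, 0, 4, 4, 4, 4, 0, 0, 2, 2, 0, 0))
  # positions in a run share its id and are contiguous
  for (rid in unique(stats::na.omit(loops$run_id))) {
    pos <- loops$pos[which(!is.na(loops$run_id) & loops$run_id == rid)]
    expect_equal(pos, seq(min(pos), max(pos)))
    expect_equal(unique(loops$run_length[pos]), length(pos))
  }

  expect_true(all(annotate_loops(parse_dotbracket("(((())))"))$run_length == 0))
})

test_that("run lengths agree with brute-force counting on generated hairpins", {
  ds <- generate_dataset(synth_params(n_precursors = 15, seed = 9))
  for (db in ds$db) {
    got <- annotate_loops(parse_dotbracket(db))$run_length
    expect_equal(got, bf_run_length(db))
  }
})

test_that("find_apex returns the innermost loop and consistent arm labels", {
  apex <- find_apex(parse_dotbracket("((..((....))..))"))
  expect_equal(apex$apex_start, 7L)
  expect_equal(apex$apex_end, 10L)
  expect_equal(apex$side, c(rep("5p", 6), rep("apex", 4), rep("3p", 6)))

  apex <- find_apex(parse_dotbracket("(.)"))
  expect_equal(c(apex$apex_start, apex$apex_end), c(2L, 2L))

  expect_error(find_apex(parse_dotbracket("...")), "no hairpin")
})

test_that("multi-hairpin structures pick the innermost pair nearest the midpoint", {
  # hairpins at 1-6 and 7-13; midpoint of the 13-mer is 7, so the loop of
  # the second hairpin (enclosed by the pair 8-12) wins
  apex <- find_apex(parse_dotbracket("((..))((...))"))
  expect_equal(c(apex$apex_start, apex$apex_end), c(9L, 11L))
})

test_that("apex flanking pairs are mutual partners on generated hairpins", {
  ds <- generate_dataset(synth_params(n_precursors = 10, seed = 21))
  for (db in ds$db) {
    pm <- parse_dotbracket(db)
    apex <- find_apex(pm)
    expect_equal(pm$partner[apex$apex_start - 1L], apex$apex_end + 1L)
  }
})

test_that("complementary segment of a fully paired window is the reversed partners", {
  hp <- perfect_hairpin(n_pairs = 16, apex = 4)
  pm <- parse_dotbracket(hp$db)
  seg <- complementary_segment(4, 6, pm)
  expect_equal(seg, pm$partner[4:9])
  expect_true(all(diff(seg) == -1))
  # involution up to orientation: partners of the segment give the window back
  back <- complementary_segment(min(seg), 6, pm)
  expect_equal(sort(back), 4:9)
})

test_that("own-strand bulge pads the apex-distal end with a gap", {
  hp <- bulge5_hairpin()
  pm <- parse_dotbracket(hp$db)
  # window 4..9 holds 5 paired positions (6 is the bulge)
  seg <- complementary_segment(4, 6, pm)
  expect_equal(seg, c(NA, 22L, 21L, 20L, 19L, 18L))
})

test_that("opposite-strand bulge widens the span, trimmed apex-distally", {
  hp <- bulge3_hairpin()
  pm <- parse_dotbracket(hp$db)
  # partners of window 3..8 span 23..17 (7 positions incl. the bulge at 20)
  seg <- complementary_segment(3, 6, pm)
  expect_equal(seg, c(22L, 21L, 20L, 19L, 18L, 17L))
})

test_that("windows facing no base pair are rejected", {
  pm <- parse_dotbracket("((..((....))..))")
  expect_error(complementary_segment(7, 4, pm), "no anchor pair")
})

test_that("max_loop_length takes the dataset-wide maximum", {
  expect_equal(max_loop_length("((..((....))..))"), 4L)
  expect_equal(max_loop_length("(((())))"), 0L)
  # runs of 2, 7 and 3 across three structures
  expect_equal(max_loop_length(c("((..))",
                                 paste0("((", strrep(".", 7), "))"),
                                 "((...))")), 7L)
  expect_error(max_loop_length(character(0)), "empty")
})
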