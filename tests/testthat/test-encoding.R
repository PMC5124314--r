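test_that("per-token patterns follow the scheme tables", {
  expect_equal(encode_token("A", 0, encoding_scheme("seq", w = 6)), c(1, 0, 0, 0))
  expect_equal(encode_token("U", 0, encoding_scheme("seq", w = 6)), c(0, 1, 0, 0))
  expect_equal(encode_token("C", 0, encoding_scheme("seq", w = 6)), c(0, 0, 1, 0))
  expect_equal(encode_token("G", 0, encoding_scheme("seq", w = 6)), c(0, 0, 0, 1))
  # structure pattern writes any loop token as all zeros
  expect_equal(encode_token("A", 3, encoding_scheme("struct", w = 6)), rep(0, 4))
  # extended pattern: the loop is the fifth symbol
  expect_equal(encode_token("A", 3, encoding_scheme("extended", w = 6)),
               c(0, 0, 0, 0, 1))
  # lbsize: L_1 with k = 3, M = 5 puts its k ones in 1-based slots 5..7
  v <- encode_token("G", 1, encoding_scheme("lbsize", w = 6, k = 3, M = 5))
  expect_equal(which(v == 1), 5:7)
  expect_equal(length(v), 11L)
  # nucleotides under lbsize stay one-hot in the first four slots
  expect_equal(encode_token("G", 0, encoding_scheme("lbsize", w = 6, k = 3, M = 5)),
               c(0, 0, 0, 1, rep(0, 7)))
  # gap placeholders are all-zero under every scheme
  for (nm in c("seq", "struct", "extended")) {
    expect_true(all(encode_token(NA, NA, encoding_scheme(nm, w = 6)) == 0))
  }
  expect_true(all(encode_token(NA, NA, encoding_scheme("lbsize", w = 6, k = 2, M = 3)) == 0))
})

test_that("loop tokens exceeding the training M are clipped with a warning", {
  sc <- encoding_scheme("lbsize", w = 6, k = 2, M = 4)
  expect_warning(v <- encode_token("A", 7, sc), "clipped")
  expect_equal(which(v == 1), (4 + 4):(2 + 3 + 4))
})

test_that("feature vector lengths follow the scheme dimensions", {
  ds <- generate_dataset(synth_params(n_precursors = 3, seed = 6))
  for (w in c(8L, 10L, 12L)) {
    win <- make_windows(ds, w = w)
    expect_equal(ncol(encode_windows(win, encoding_scheme("seq", w = w))$x), 4L * w)
    expect_equal(ncol(encode_windows(win, encoding_scheme("struct", w = w))$x), 8L * w)
    expect_equal(ncol(encode_windows(win, encoding_scheme("extended", w = w))$x), 10L * w)
    for (k in c(1L, 4L)) {
      f <- encode_windows(win, encoding_scheme("lbsize", w = w, k = k))
      expect_equal(ncol(f$x), 2L * w * (f$scheme$M + k + 3L))
    }
  }
})

test_that("lbsize M resolves from the training windows and is kept in the scheme", {
  ds <- generate_dataset(synth_params(n_precursors = 5, seed = 8))
  win <- make_windows(ds, w = 10)
  sc <- resolve_scheme(encoding_scheme("lbsize", w = 10, k = 2), win)
  expect_equal(sc$M, max(c(unlist(win$arm_l), unlist(win$comp_l)), na.rm = TRUE))
  # a preset M is not overridden
  sc5 <- resolve_scheme(encoding_scheme("lbsize", w = 10, k = 2, M = 9), win)
  expect_equal(sc5$M, 9L)
})

test_that("closed-form kernel identities match brute force on encoded tokens", {
  for (k in 1:5) {
    sc <- encoding_scheme("lbsize", w = 6, k = k, M = 10)
    for (l1 in 1:10) {
      v1 <- encode_token("A", l1, sc)
      for (l2 in 1:10) {
        v2 <- encode_token("A", l2, sc)
        expect_equal(sum(v1 * v2), loop_dot(l1, l2, k))
        expect_equal(sum(v1 * v2), max(k - abs(l1 - l2), 0))
        expect_equal(sum((v1 - v2)^2), loop_sqdist(l1, l2, k))
        expect_equal(sum((v1 - v2)^2), 2 * min(abs(l1 - l2), k))
      }
    }
  }
})

test_that("loop kernel is monotone in the length difference and saturates", {
  k <- 3
  deltas <- 0:8
  dots <- loop_dot(1, 1 + deltas, k)
  dists <- loop_sqdist(1, 1 + deltas, k)
  expect_true(all(diff(dots) <= 0))
  expect_true(all(diff(dists) >= 0))
  expect_equal(max(dists), 2 * k)
  expect_equal(loop_dot(2, 5, 2), 0)       # |delta| >= k: no overlap
  expect_equal(loop_dot(4, 4, 5), 5)       # equal lengths: full overlap k
  expect_equal(loop_sqdist(6, 6, 2), 0)
})

test_that("lbsize with k = 1 collapses to the extended pattern when all loops have l = 1", {
  ext <- encoding_scheme("extended", w = 6)
  lb1 <- encoding_scheme("lbsize", w = 6, k = 1, M = 1)
  for (nt in c("A", "U", "C", "G")) {
    expect_equal(encode_token(nt, 0, lb1), encode_token(nt, 0, ext))
    expect_equal(encode_token(nt, 1, lb1), encode_token(nt, 1, ext))
  }
})

test_that("lbsize token vectors hold exactly 1, k, or 0 ones", {
  sc <- encoding_scheme("lbsize", w = 6, k = 4, M = 6)
  expect_equal(sum(encode_token("C", 0, sc)), 1)
  for (l in 1:6) expect_equal(sum(encode_token("C", l, sc)), 4)
  expect_equal(sum(encode_token(NA, NA, sc)), 0)
})

test_that("worked-example fixture tokenizes and encodes as published", {
  fx <- fixture_fig1()
  expect_equal(fx$arm_tokens[fx$arm == "5p"], "L1 G G G L1 G")
  expect_equal(fx$arm_tokens[fx$arm == "3p"], "C G U C A U")
  expect_equal(attr(fx, "w"), 6L)
  expect_equal(attr(fx, "k"), 3L)

  for (M in c(1L, 4L, 9L)) {
    f <- encode_windows(fx, encoding_scheme("lbsize", w = 6, k = 3, M = M))
    arm_len <- ncol(f$x) / 2
    expect_equal(arm_len, 6 * (M + 6))   # per-arm lbsize length 6(M+6)
    # the 3p window is six plain one-hots: one 1 in the first 4 slots per token
    v3 <- f$x[f$meta$arm == "3p", seq_len(arm_len)]
    tok <- matrix(v3, nrow = 6, byrow = TRUE)
    expect_true(all(rowSums(tok) == 1))
    expect_true(all(tok[, 5:(M + 6)] == 0))
  }
})

test_that("the printed RBF shortcut disagrees with the encoding; the distance rule holds", {
  # exp(-gamma ||x1-x2||^2) with the true distance 2*min(|l1-l2|, k) differs
  # from the printed shortcut exp(-4*gamma*min((l1-l2)^2, k^2)): recorded as
  # an erratum, the encoding itself is authoritative.
  k <- 3
  sc <- encoding_scheme("lbsize", w = 6, k = k, M = 10)
  mism <- 0L
  for (l1 in 1:8) for (l2 in 1:8) {
    d2 <- sum((encode_token("A", l1, sc) - encode_token("A", l2, sc))^2)
    expect_equal(d2, 2 * min(abs(l1 - l2), k))
    if (d2 != 4 * min((l1 - l2)^2, k^2)) mism <- mism + 1L
  }
  expect_gt(mism, 0L)
})
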