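test_that("metric formulas follow their definitions", {
  m <- compute_metrics(tp = 50, tn = 50, fp = 0, fn = 0)
  expect_equal(unlist(m), c(sn = 1, sp = 1, ac = 1, mcc = 1))

  m <- compute_metrics(tp = 3, tn = 0, fp = 0, fn = 1)
  expect_equal(m$sn, 0.75)
  expect_equal(m$mcc, 0)   # zero factor in the denominator

  m <- compute_metrics(tp = 8, tn = 7, fp = 2, fn = 3)
  expect_equal(m$sn, 8 / 11)
  expect_equal(m$sp, 7 / 9)
  expect_equal(m$ac, 15 / 20)
  expect_equal(m$mcc, (8 * 7 - 2 * 3) / sqrt(10 * 11 * 9 * 10))

  expect_error(compute_metrics(0, 0, 0, 0), "no evaluated")
})

test_that("metrics agree with per-example tallies on random confusion tables", {
  withr::with_seed(99, {
    for (rep in 1:1000) {
      n <- sample(4:40, 1)
      label <- sample(c(-1L, 1L), n, replace = TRUE)
      pred <- sample(c(-1L, 1L), n, replace = TRUE)
      tp <- sum(pred == 1 & label == 1); tn <- sum(pred == -1 & label == -1)
      fp <- sum(pred == 1 & label == -1); fn <- sum(pred == -1 & label == 1)
      m <- compute_metrics(tp, tn, fp, fn)
      expect_equal(m$ac, mean(pred == label))
      if (tp + fn > 0) expect_equal(m$sn, mean(pred[label == 1] == 1))
      if (tn + fp > 0) expect_equal(m$sp, mean(pred[label == -1] == -1))
      expect_true(m$mcc >= -1 && m$mcc <= 1)
      # MCC is the Pearson correlation of prediction and label indicators
      if (stats::sd(pred) > 0 && stats::sd(label) > 0) {
        expect_equal(m$mcc, suppressWarnings(stats::cor(pred, label)))
      }
    }
  })
})

test_that("the SVM separates separable data and fails on contradictory labels", {
  sep <- manual_windows(list(rep("A", 4), rep("U", 4)), c(1, -1))
  m <- cleav_fit(sep, encoding_scheme("seq", w = 4), cost = 100)
  expect_equal(predict(m, sep)$pred, c(1L, -1L))

  contra <- manual_windows(list(rep("A", 4), rep("A", 4)), c(1, -1))
  m2 <- cleav_fit(contra, encoding_scheme("seq", w = 4), cost = 100)
  expect_equal(mean(predict(m2, contra)$pred == contra$label), 0.5)

  single <- manual_windows(list(rep("A", 4), rep("U", 4)), c(1, 1))
  expect_error(cleav_fit(single, encoding_scheme("seq", w = 4)), "both classes")
})

test_that("RBF kernel fits an XOR arrangement that defeats a linear rule", {
  xor <- manual_windows(
    list(c("A", "A"), c("U", "U"), c("A", "U"), c("U", "A")),
    c(1, 1, -1, -1)
  )
  sc <- encoding_scheme("seq", w = 2)
  m <- cleav_fit(xor, sc, gamma = 1, cost = 100)
  expect_equal(predict(m, xor)$pred, xor$label)

  # independent reference: kernlab on the identical feature matrix
  f <- encode_windows(xor, sc)
  ref <- kernlab::ksvm(f$x, factor(f$y), kernel = "rbfdot",
                       kpar = list(sigma = 1), C = 100, scaled = FALSE)
  expect_equal(as.integer(as.character(ref@fitted)), xor$label)
})

test_that("decision scores are unchanged by all-zero feature columns", {
  ds <- generate_dataset(synth_params(n_precursors = 12, seed = 31))
  win <- make_windows(ds, w = 10)
  m_small <- cleav_fit(win, resolve_scheme(encoding_scheme("lbsize", w = 10, k = 2), win))
  m_big <- cleav_fit(win, encoding_scheme("lbsize", w = 10, k = 2,
                                          M = m_small$scheme$M + 5L),
                     gamma = m_small$gamma)
  expect_equal(predict(m_small, win)$score, predict(m_big, win)$score,
               tolerance = 1e-8)
})

test_that("roc_curve sweeps thresholds correctly", {
  labs <- c(1, 1, -1, -1)
  r <- roc_curve(c(1, 1, -1, -1), labs)
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))

  # reversing the scores mirrors the curve
  withr::with_seed(7, {
    s <- stats::rnorm(100)
    y <- sample(c(-1, 1), 100, replace = TRUE)
  })
  expect_equal(roc_curve(-s, y)$auc, 1 - roc_curve(s, y)$auc)

  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is near 1/2 for label-independent scores and matches pROC", {
  withr::with_seed(11, {
    s <- stats::rnorm(1000)
    y <- sample(c(-1, 1), 1000, replace = TRUE)
  })
  expect_lt(abs(roc_curve(s, y)$auc - 0.5), 0.05)

  withr::with_seed(12, {
    s2 <- sample(seq(-1, 1, by = 0.25), 200, replace = TRUE)  # many ties
    y2 <- sample(c(-1, 1), 200, replace = TRUE)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(response = y2, predictor = s2,
                                        quiet = TRUE, direction = "<")))
  expect_equal(roc_curve(s2, y2)$auc, ref, tolerance = 1e-12)
})

test_that("cross-validation splits by precursor and balances folds", {
  ds <- generate_dataset(synth_params(n_precursors = 10, seed = 17))
  win <- make_windows(ds, w = 10)
  cv <- cross_validate(win, encoding_scheme("lbsize", w = 10, k = 3), seed = 3)
  # 10 precursors over 5 folds: 2 test precursors = 4 windows per fold/arm
  expect_true(all(with(cv$per_fold, tp + tn + fp + fn) == 4L))
  # every precursor held out exactly once per arm
  fa <- cv$folds_assignment
  expect_equal(nrow(fa), 20L)
  expect_true(all(dplyr::count(fa, arm, id)$n == 1L))
  expect_error(cross_validate(win, encoding_scheme("seq", w = 10), folds = 11),
               "fewer precursors")
})

test_that("a planted deterministic signal is learned perfectly", {
  # no background bulges: the cue is the only loop, so classes are cleanly
  # separable and every fold classifies perfectly
  ds <- generate_dataset(synth_params(n_precursors = 15, signal_strength = 1,
                                      bulge_rate = 0, seed = 23))
  win <- make_windows(ds, w = 10)
  cv <- cross_validate(win, encoding_scheme("lbsize", w = 10, k = 3), seed = 2)
  g <- glance(cv)
  expect_equal(g$ac, c(1, 1))
  expect_equal(g$var_ac, c(0, 0))
})

test_that("a null dataset scores at chance", {
  ds <- generate_dataset(synth_params(n_precursors = 200, signal_strength = 0,
                                      seed = 29))
  win <- make_windows(ds, w = 10)
  cv <- cross_validate(win, encoding_scheme("lbsize", w = 10, k = 3), seed = 5)
  expect_true(all(abs(glance(cv)$ac - 0.5) <= 0.1))
})

test_that("leave-one-precursor-out agrees with fivefold within sampling noise", {
  ds <- generate_dataset(synth_params(n_precursors = 24, signal_strength = 0.9,
                                      seed = 37))
  win <- make_windows(ds, w = 10)
  sc <- encoding_scheme("lbsize", w = 10, k = 3)
  ac5 <- glance(cross_validate(win, sc, folds = 5, seed = 8))$ac
  acn <- glance(cross_validate(win, sc, folds = 24, seed = 8))$ac
  expect_true(all(abs(ac5 - acn) < 0.15))
})

test_that("lbsize(k=1) and extended give identical CV metrics when all loops are 1 nt", {
  ds <- generate_dataset(synth_params(n_precursors = 25, signal_strength = 0.8,
                                      bulge_len_max = 1, apex_range = c(4, 4),
                                      signature_length = 1, seed = 41))
  win <- make_windows(ds, w = 8)
  cv_lb <- cross_validate(win, encoding_scheme("lbsize", w = 8, k = 1),
                          gamma = 0.01, cost = 1, seed = 6)
  cv_ext <- cross_validate(win, encoding_scheme("extended", w = 8),
                           gamma = 0.01, cost = 1, seed = 6)
  expect_equal(tidy(cv_lb), tidy(cv_ext))
})
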