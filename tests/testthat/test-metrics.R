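test_that("Dice has exact reference cases including the shifted square", {
  a <- array(0L, c(8, 8, 1)); a[3:4, 3:4, 1] <- 3L
  b <- array(0L, c(8, 8, 1)); b[3:4, 4:5, 1] <- 3L     # shifted one voxel
  expect_equal(dsc(a, b, 3L), 0.5)
  expect_equal(dsc(a, a, 3L), 1)
  disj <- array(0L, c(8, 8, 1)); disj[7:8, 7:8, 1] <- 3L
  expect_equal(dsc(a, disj, 3L), 0)
  expect_equal(dsc(a, b, 4L), 1)                       # both empty: agreement
  expect_equal(dsc(a, b, 3L), dsc(b, a, 3L))           # symmetry
  expect_error(dsc(a, array(0L, c(4, 4, 1)), 3L), "shape")
})

test_that("Hausdorff distance has exact geometric references", {
  a <- array(0L, c(8, 8, 3)); a[1, 1, 1] <- 2L
  b <- array(0L, c(8, 8, 3)); b[4, 5, 1] <- 2L         # 3-4-5 triangle
  expect_equal(hausdorff(a, b, 2L, spacing = c(1, 1, 1)), 5)
  expect_equal(hausdorff(a, a, 2L, spacing = c(1, 1, 1)), 0)
  expect_true(is.na(hausdorff(a, array(0L, c(8, 8, 3)), 2L, spacing = c(1, 1, 1))))
  # spacing scales distances into mm
  expect_equal(hausdorff(a, b, 2L, spacing = c(2, 1, 1)), sqrt(36 + 16))
})

test_that("Hausdorff agrees with the brute-force pairwise oracle", {
  set.seed(23)
  sp <- c(1.5, 1.5, 8)
  for (i in 1:6) {
    p <- random_label_map(c(9, 9, 3), values = 0:2, p = c(0.7, 0.1, 0.2))
    g <- random_label_map(c(9, 9, 3), values = 0:2, p = c(0.7, 0.1, 0.2))
    if (!any(p == 2L) || !any(g == 2L)) next
    expect_equal(hausdorff(p, g, 2L, spacing = sp),
                 oracle_hausdorff(p, g, 2L, sp), tolerance = 1e-9)
    d1 <- hausdorff(p, g, 2L, spacing = sp, mode = "directed")
    expect_equal(d1, oracle_hausdorff(p, g, 2L, sp, mode = "directed"),
                 tolerance = 1e-9)
    expect_gte(hausdorff(p, g, 2L, spacing = sp), d1)   # symmetric >= directed
  }
})

test_that("volume differences follow the worked arithmetic", {
  # 120 vs 100 predicted/manual voxels at unit spacing, 1000-voxel myocardium
  g <- array(0L, c(12, 12, 10))
  g[1:10, 1:10, 1:10] <- 2L                  # 1000 myocardium voxels
  g[1:10, 1:10, 1] <- 3L                     # 100 of them scar
  p <- g
  p[1:10, 1:2, 2] <- 3L                      # +20 voxels scar
  out <- avd_avdr(p, g, class_set = 3L, spacing = c(1, 1, 1))
  expect_equal(out[["avd"]], 20)
  expect_equal(out[["avdr"]], 100 * 20 / 1000)
  expect_equal(avd_avdr(g, g, class_set = 3L, spacing = c(1, 1, 1))[["avd"]], 0)
  # symmetric in (p, g)
  expect_equal(avd_avdr(g, p, class_set = 3L, spacing = c(1, 1, 1))[["avd"]], 20)
  # AVDR halves when the reference myocardium doubles at fixed AVD
  g2 <- array(0L, c(12, 12, 20)); g2[1:10, 1:10, 1:20] <- 2L
  g2[1:10, 1:10, 1] <- 3L
  p2 <- g2; p2[1:10, 1:2, 2] <- 3L
  expect_equal(avd_avdr(p2, g2, 3L, c(1, 1, 1))[["avdr"]],
               out[["avdr"]] / 2, tolerance = 1e-9)
})

test_that("MVO presence accuracy counts cases and slices", {
  mk <- function(mvo_slices) {
    lab <- array(0L, c(6, 6, 4))
    for (s in mvo_slices) lab[3, 3, s] <- 4L
    lab
  }
  gts <- list(mk(1), mk(integer(0)), mk(2:3), mk(integer(0)), mk(1:4))
  preds <- list(mk(1), mk(4), mk(integer(0)), mk(integer(0)), mk(1:4))
  expect_equal(mvo_presence_accuracy(preds, gts, "case"), 100 * 3 / 5)
  # slice level: brute-force tally
  tot <- 0; ok <- 0
  for (i in 1:5) for (s in 1:4) {
    tot <- tot + 1
    ok <- ok + (any(preds[[i]][, , s] == 4L) == any(gts[[i]][, , s] == 4L))
  }
  expect_equal(mvo_presence_accuracy(preds, gts, "slice"), 100 * ok / tot)
  expect_equal(mvo_presence_accuracy(gts, gts, "case"), 100)
})

test_that("classification metrics match the hand-built confusion matrix", {
  truth <- c(rep("infarcted", 4), rep("normal", 6))
  pred <- c("infarcted", "infarcted", "infarcted", "normal",   # TP 3, FN 1
            "infarcted", rep("normal", 5))                     # FP 1, TN 5
  m <- classification_metrics(pred, truth)
  expect_equal(m[["sensitivity"]], 75)
  expect_equal(m[["specificity"]], 100 * 5 / 6, tolerance = 1e-9)
  expect_equal(m[["precision"]], 75)
  expect_equal(m[["accuracy"]], 80)
  all_ok <- classification_metrics(truth, truth)
  expect_true(all(all_ok == 100))
  # no positives in truth: sensitivity undefined
  m2 <- classification_metrics(rep("normal", 3), rep("normal", 3))
  expect_true(is.na(m2[["sensitivity"]]))
  # random labellings against a looped confusion matrix
  set.seed(31)
  for (i in 1:10) {
    t2 <- sample(c("normal", "infarcted"), 20, TRUE)
    p2 <- sample(c("normal", "infarcted"), 20, TRUE)
    m3 <- classification_metrics(p2, t2)
    tp <- sum(p2 == "infarcted" & t2 == "infarcted")
    fp <- sum(p2 == "infarcted" & t2 == "normal")
    fn <- sum(p2 == "normal" & t2 == "infarcted")
    tn <- sum(p2 == "normal" & t2 == "normal")
    expect_equal(m3[["accuracy"]], 100 * (tp + tn) / 20)
    if (tp + fn > 0) expect_equal(m3[["sensitivity"]], 100 * tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m3[["specificity"]], 100 * tn / (tn + fp))
  }
})

test_that("Bland-Altman summaries follow the textbook arithmetic", {
  ba0 <- bland_altman(c(10, 20, 30), c(10, 20, 30))
  expect_equal(ba0$bias, 0); expect_equal(ba0$lower, 0); expect_equal(ba0$upper, 0)
  ba <- bland_altman(c(11, 22, 33), c(10, 20, 30))   # differences 1, 2, 3
  expect_equal(ba$bias, 2)
  expect_equal(ba$lower, 2 - 1.96, tolerance = 1e-9)
  expect_equal(ba$upper, 2 + 1.96, tolerance = 1e-9)
  # shifting both series leaves the differences untouched
  ba2 <- bland_altman(c(11, 22, 33) + 100, c(10, 20, 30) + 100)
  expect_equal(ba2$bias, ba$bias)
  expect_equal(ba2$lower, ba$lower)
  expect_equal(ba$pairs$average, c(10.5, 21, 31.5))
})

test_that("Dice agrees with a per-voxel oracle on random masks", {
  set.seed(37)
  for (i in 1:8) {
    p <- random_label_map(c(10, 10, 4))
    g <- random_label_map(c(10, 10, 4))
    for (cls in list(2L, c(3L, 4L))) {
      expect_equal(dsc(p, g, cls), oracle_dsc(p, g, cls), tolerance = 1e-12)
    }
  }
})
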