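rand_probs <- function(K, dims) {
  p <- array(runif(K * prod(dims)), c(K, dims))
  s <- colSums(matrix(p, K))
  p / rep(s, each = K)
}

test_that("Dice loss attains -1 at a perfect one-hot prediction", {
  lab <- array(sample(0:3, 4^3, TRUE), c(4, 4, 4))   # all classes present
  v <- onehot_encode(lab, classes = 0:3)
  expect_equal(loss_dice(v, v), -1, tolerance = 1e-4)
  # zero mass on every true class gives 0
  flip <- onehot_encode((lab + 1L) %% 4L, classes = 0:3)
  expect_equal(loss_dice(flip, v), 0, tolerance = 1e-6)
})

test_that("Dice loss is bounded and matches brute-force class sums", {
  set.seed(11)
  for (i in 1:10) {
    lab <- array(sample(0:3, 8^3, TRUE), c(8, 8, 8))
    v <- onehot_encode(lab, classes = 0:3)
    u <- rand_probs(4, c(8, 8, 8))
    val <- loss_dice(u, v)
    expect_gte(val, -1); expect_lte(val, 0)
    # brute force: per-class sums with explicit loops over classes
    acc <- 0
    for (k in 1:4) {
      num <- sum(u[k, , , ] * v[k, , , ])
      den <- sum(u[k, , , ]) + sum(v[k, , , ]) + 1e-6
      acc <- acc + num / den
    }
    expect_equal(val, -2 / 4 * acc, tolerance = 1e-12)
  }
})

test_that("cross-entropy loss has exact reference values", {
  lab <- array(sample(0:3, 27, TRUE), c(3, 3, 3))
  v <- onehot_encode(lab, classes = 0:3)
  expect_equal(loss_ce(v * 0 + 0.25, v), log(4), tolerance = 1e-12)
  expect_lt(loss_ce(pmin(v + 1e-9, 1), v), 1e-6)
  # two-voxel hand computation
  v2 <- onehot_encode(array(c(0L, 1L), c(2, 1, 1)), classes = 0:1)
  u2 <- array(c(0.8, 0.2, 0.3, 0.7), c(2, 2, 1, 1))
  expect_equal(loss_ce(u2, v2), -(log(0.8) + log(0.7)) / 2, tolerance = 1e-12)
  expect_equal(loss_anatomical(u2, v2), loss_ce(u2, v2) + loss_dice(u2, v2))
})

test_that("soft-IoU loss reproduces the single-voxel hand example", {
  # one voxel, two classes, p = (0.5, 0.5), true class first:
  # overlaps (0.5, 0), mean 0.25, loss 0.75
  p <- array(c(0.5, 0.5), c(2, 1, 1, 1))
  g <- array(c(1, 0), c(2, 1, 1, 1))
  expect_equal(soft_iou_overlap(p, g), 0.25, tolerance = 1e-6)
  expect_equal(loss_soft_iou(p, g), 0.75, tolerance = 1e-6)
  # perfect one-hot prediction: overlap 1 per present class, loss 0
  lab <- array(sample(0:3, 64, TRUE), c(4, 4, 4))
  v <- onehot_encode(lab, classes = 0:3)
  expect_equal(loss_soft_iou(v, v), 0, tolerance = 1e-4)
})

test_that("soft-IoU loss is bounded and matches brute-force voxel sums", {
  set.seed(13)
  for (i in 1:10) {
    lab <- array(sample(0:2, 8^3, TRUE), c(8, 8, 8))
    g <- onehot_encode(lab, classes = 0:2)
    p <- rand_probs(3, c(8, 8, 8))
    val <- loss_soft_iou(p, g)
    expect_gte(val, 0); expect_lte(val, 1)
    acc <- 0
    for (k in 1:3) {
      num <- sum(p[k, , , ] * g[k, , , ])
      den <- sum(p[k, , , ] + g[k, , , ] - p[k, , , ] * g[k, , , ]) + 1e-6
      acc <- acc + num / den
    }
    expect_equal(val, 1 - acc / 3, tolerance = 1e-12)
  }
})

test_that("inclusion loss is the summed squared Frobenius norm", {
  r <- array(runif(4 * 6 * 6 * 2), c(4, 6, 6, 2))
  expect_equal(loss_inclusion(r, r), 0)
  r2 <- r; r2[2, 3, 3, 1] <- r[2, 3, 3, 1] + 2
  expect_equal(loss_inclusion(r2, r), 4, tolerance = 1e-12)
  set.seed(5)
  a <- array(runif(3 * 8 * 8 * 8), c(3, 8, 8, 8))
  b <- array(runif(3 * 8 * 8 * 8), c(3, 8, 8, 8))
  brute <- 0
  for (i in seq_along(a)) brute <- brute + (a[i] - b[i])^2
  expect_equal(loss_inclusion(a, b), brute, tolerance = 1e-9)
  # batch form sums over volumes
  expect_equal(loss_inclusion(list(a, a), list(b, b)),
               2 * loss_inclusion(a, b))
})

test_that("classification loss matches hand-computed cross-entropy", {
  expect_equal(loss_class(c(0, 0), "infarcted"), log(2), tolerance = 1e-12)
  s <- c(2.0, -1.0)
  q <- exp(s) / sum(exp(s))
  expect_equal(loss_class(s, "normal"), -log(q[1]), tolerance = 1e-12)
  expect_lt(loss_class(c(-20, 20), "infarcted"), 1e-6)
})

test_that("final loss reduces at zero weights and is linear in each lambda", {
  set.seed(17)
  lab <- array(sample(0:3, 64, TRUE), c(4, 4, 4))
  g <- onehot_encode(lab, classes = 0:3)
  p <- rand_probs(4, c(4, 4, 4))
  rp <- array(runif(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  rg <- array(runif(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  sc <- c(0.3, -0.2)
  expect_equal(loss_final(p, g, rp, rg, sc, "infarcted", loss_weights(0, 0)),
               loss_soft_iou(p, g))
  # perfect prediction, identical reconstructions, confident correct class
  expect_lt(loss_final(g, g, rp, rp, c(-30, 30), "infarcted",
                       loss_weights(0.3, 0.3)), 1e-4)
  # two-point slope check in lambda_ic at fixed inputs
  l1 <- loss_final(p, g, rp, rg, sc, "normal", loss_weights(0.1, 0.2))
  l2 <- loss_final(p, g, rp, rg, sc, "normal", loss_weights(0.3, 0.2))
  slope <- (l2 - l1) / 0.2
  expect_equal(slope, loss_inclusion(rp, rg), tolerance = 1e-8)
  l3 <- loss_final(p, g, rp, rg, sc, "normal", loss_weights(0.1, 0.4))
  expect_equal((l3 - l1) / 0.2, loss_class(sc, "normal"), tolerance = 1e-8)
})

test_that("losses stay finite on empty-class fixtures", {
  g <- array(0, c(3, 4, 4, 2)); g[1, , , ] <- 1      # only class 1 present
  p <- rand_probs(3, c(4, 4, 2))
  for (val in c(loss_dice(p, g), loss_ce(p, g), loss_soft_iou(p, g)))
    expect_true(is.finite(val))
})
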