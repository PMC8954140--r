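# The conv engine is pinned by (i) a naive R convolution oracle and (ii)
# finite-difference gradient checks through whole networks.

naive_conv3d <- function(x, W, b, k, s, p) {
  d <- dim(x)
  C <- d[1]
  Xo <- (d[2] + 2 * p[1] - k[1]) %/% s[1] + 1
  Yo <- (d[3] + 2 * p[2] - k[2]) %/% s[2] + 1
  Zo <- (d[4] + 2 * p[3] - k[3]) %/% s[3] + 1
  Cout <- nrow(W)
  y <- array(0, c(Cout, Xo, Yo, Zo))
  for (oz in 1:Zo) for (oy in 1:Yo) for (ox in 1:Xo) for (co in 1:Cout) {
    acc <- b[co]
    for (iz in 1:k[3]) for (iy in 1:k[2]) for (ix in 1:k[1]) for (ci in 1:C) {
      xi <- (ox - 1) * s[1] - p[1] + ix
      yi <- (oy - 1) * s[2] - p[2] + iy
      zi <- (oz - 1) * s[3] - p[3] + iz
      if (xi < 1 || xi > d[2] || yi < 1 || yi > d[3] || zi < 1 || zi > d[4]) next
      wcol <- ci + C * ((ix - 1) + k[1] * ((iy - 1) + k[2] * (iz - 1)))
      acc <- acc + W[co, wcol] * x[ci, xi, yi, zi]
    }
    y[co, ox, oy, oz] <- acc
  }
  y
}

test_that("the C++ convolution matches a naive R convolution", {
  set.seed(61)
  for (cfg in list(list(k = c(3L, 3L, 3L), s = c(1L, 1L, 1L), p = c(1L, 1L, 1L)),
                   list(k = c(3L, 3L, 1L), s = c(2L, 2L, 1L), p = c(1L, 1L, 0L)))) {
    x <- array(rnorm(2 * 6 * 6 * 4), c(2, 6, 6, 4))
    W <- matrix(rnorm(3 * 2 * prod(cfg$k)), nrow = 3)
    b <- rnorm(3)
    y <- lgeseg:::nn_conv_fwd(x, dim(x), W, b, cfg$k, cfg$s, cfg$p)
    expect_equal(array(y, dim(y)), naive_conv3d(x, W, b, cfg$k, cfg$s, cfg$p),
                 tolerance = 1e-12)
  }
})

test_that("pooling and upsampling are exact inverduals on indicator grids", {
  set.seed(67)
  x <- array(rnorm(3 * 8 * 8 * 4), c(3, 8, 8, 4))
  pl <- lgeseg:::nn_pool_fwd(x, dim(x), c(2L, 2L, 2L))
  # every pooled value is the max of its 2x2x2 block
  for (t in 1:20) {
    i <- sample(3, 1); ox <- sample(4, 1); oy <- sample(4, 1); oz <- sample(2, 1)
    blk <- x[i, (2 * ox - 1):(2 * ox), (2 * oy - 1):(2 * oy), (2 * oz - 1):(2 * oz)]
    expect_equal(pl$y[i, ox, oy, oz], max(blk))
  }
  # upsample replicates nearest neighbours
  u <- lgeseg:::nn_upsample_fwd(pl$y, dim(pl$y), c(2L, 2L, 2L))
  expect_equal(dim(u), dim(x))
  expect_equal(u[1, 1, 1, 1], u[1, 2, 2, 2])
  # pool backward scatters into argmax positions only
  dy <- array(1, dim(pl$y))
  dx <- lgeseg:::nn_pool_bwd(dy, pl$idx, dim(x))
  expect_equal(sum(dx), length(pl$y))
  expect_true(all(dx %in% c(0, 1)))
})

test_that("built networks satisfy the softmax and sizing contracts", {
  cfg <- net_config("unet3d", in_channels = 1, out_classes = 4, depth = 2,
                    base_channels = 4)
  net <- build_net(cfg, seed = 1)
  x <- array(rnorm(1 * 16 * 16 * 8), c(1, 16, 16, 8))
  probs <- lgeseg:::unet_forward(net, list(x))$probs[[1]]
  expect_equal(dim(probs), c(4L, 16L, 16L, 8L))
  expect_silent(validate_probmap(probs))
  # parameter count grows monotonically with base_channels
  n1 <- n_params(build_net(net_config(base_channels = 4), seed = 1))
  n2 <- n_params(build_net(net_config(base_channels = 8), seed = 1))
  n3 <- n_params(build_net(net_config(base_channels = 16), seed = 1))
  expect_true(n1 < n2 && n2 < n3)
  # non-divisible input shape is rejected with the required padding stated
  bad <- array(rnorm(1 * 15 * 16 * 8), c(1, 15, 16, 8))
  expect_error(lgeseg:::unet_forward(net, list(bad)), "divisible")
})

test_that("backward gradients agree with finite differences", {
  set.seed(71)
  for (cfg in list(net_config("unet3d", in_channels = 1, out_classes = 3,
                              depth = 1, base_channels = 2, norm = "instance",
                              slope = 0.01, down = "conv", classifier = TRUE),
                   net_config("unet3d", in_channels = 2, out_classes = 4,
                              depth = 1, base_channels = 2, norm = "batch",
                              slope = 0, down = "pool"))) {
    net <- build_net(cfg, seed = 2)
    x <- array(rnorm(cfg$in_channels * 4 * 4 * 2), c(cfg$in_channels, 4, 4, 2))
    v <- onehot_encode(array(sample(0:(cfg$out_classes - 1), 32, TRUE), c(4, 4, 2)),
                       classes = 0:(cfg$out_classes - 1))
    lossfun <- function(net) {
      fw <- lgeseg:::unet_forward(net, list(x), train = TRUE)
      l <- loss_anatomical(fw$probs[[1]], v)
      if (cfg$classifier) l <- l + 0.3 * loss_class(fw$cls_scores[[1]], "infarcted")
      l
    }
    fw <- lgeseg:::unet_forward(net, list(x), train = TRUE)
    dlog <- list(lgeseg:::grad_anatomical_logits(fw$probs[[1]], v))
    dcls <- if (cfg$classifier)
      list(0.3 * lgeseg:::grad_class_scores(fw$cls_scores[[1]], "infarcted"))
    bw <- lgeseg:::unet_backward(net, fw$cache, dlog, dcls = dcls)
    # spot-check a few parameters per block family
    checks <- list(c("enc", 1L, "a", "W"), c("up", 1L, "W"),
                   c("cat_a", 1L, "b"), c("out", "W"))
    for (pa in checks) {
      w <- net$params; g <- bw$grads
      for (key in pa) {
        key2 <- if (grepl("^[0-9]+$", key)) as.integer(key) else key
        w <- w[[key2]]; g <- g[[key2]]
      }
      j <- sample(length(w), 1)
      eps <- 1e-5
      n2 <- net
      poke <- function(net, pa, j, delta) {
        expr <- net$params
        path <- lapply(pa, function(k) if (grepl("^[0-9]+$", k)) as.integer(k) else k)
        setv <- function(p, path, j, delta) {
          if (length(path) == 1L) { p[[path[[1]]]][j] <- p[[path[[1]]]][j] + delta; return(p) }
          p[[path[[1]]]] <- setv(p[[path[[1]]]], path[-1], j, delta)
          p
        }
        net$params <- setv(net$params, path, j, delta)
        net
      }
      lp <- lossfun(poke(net, pa, j, eps))
      lm <- lossfun(poke(net, pa, j, -eps))
      expect_equal(g[j], (lp - lm) / (2 * eps), tolerance = 1e-3)
    }
  }
})

test_that("one gradient step reduces the loss on a fixed sample", {
  set.seed(73)
  cfg <- net_config("unet3d", in_channels = 1, out_classes = 3, depth = 1,
                    base_channels = 4)
  net <- build_net(cfg, seed = 3)
  x <- array(rnorm(1 * 8 * 8 * 4), c(1, 8, 8, 4))
  v <- onehot_encode(array(sample(0:2, 8 * 8 * 4, TRUE), c(8, 8, 4)), classes = 0:2)
  st <- lgeseg:::adam_init(net$params)
  fw <- lgeseg:::unet_forward(net, list(x), train = TRUE)
  l0 <- loss_anatomical(fw$probs[[1]], v)
  bw <- lgeseg:::unet_backward(net, fw$cache,
                               list(lgeseg:::grad_anatomical_logits(fw$probs[[1]], v)))
  upd <- lgeseg:::adam_step(net$params, bw$grads, st, 1e-2)
  net$params <- upd$params
  l1 <- loss_anatomical(lgeseg:::unet_forward(net, list(x))$probs[[1]], v)
  expect_lt(l1, l0)
})

test_that("sliding-window prediction keeps probabilities normalised", {
  cfg <- net_config("unet3d", in_channels = 1, out_classes = 3, depth = 1,
                    base_channels = 4)
  net <- build_net(cfg, seed = 4)
  x <- array(rnorm(1 * 16 * 16 * 4), c(1, 16, 16, 4))
  pr <- lgeseg:::unet_predict(net, x, window = c(8L, 8L, 4L), stride = c(4L, 4L, 4L))
  expect_equal(dim(pr), c(3L, 16L, 16L, 4L))
  expect_silent(validate_probmap(pr, tol = 1e-6))
  # deterministic for fixed weights and input
  pr2 <- lgeseg:::unet_predict(net, x, window = c(8L, 8L, 4L), stride = c(4L, 4L, 4L))
  expect_identical(pr, pr2)
})
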