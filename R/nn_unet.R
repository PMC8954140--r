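# Encoder-decoder segmentation networks with skip connections.
#
# Two families are configured through build_net():
#  * anatomical style  — instance norm, leaky ReLU (slope 0.01), strided-conv
#    downsampling (the nnU-Net recipe);
#  * pathological style — batch norm, ReLU, max-pool downsampling.
# "unet2d" uses in-plane 3x3 kernels (no mixing across slices), "unet3d" full
# 3x3x3 kernels.

#' Network configuration
#'
#' @param kind one of `"unet2d"`, `"unet3d"`, `"cvae"`, `"classifier"` (a
#'   classifier is a U-Net with `classifier = TRUE`).
#' @param in_channels,out_classes input channels and softmax output classes.
#' @param depth number of pooling levels (default 2).
#' @param base_channels channels at the top level; doubled per level.
#' @param norm `"instance"`, `"batch"` or `"none"`.
#' @param slope leaky-ReLU slope (0 for plain ReLU).
#' @param down `"conv"` (strided convolution) or `"pool"` (max-pooling).
#' @param classifier attach a 2-class patient head to the bottleneck.
#' @return a `net_config` list.
#' @export
net_config <- function(kind = c("unet3d", "unet2d"), in_channels = 1L,
                       out_classes = 4L, depth = 2L, base_channels = 8L,
                       norm = c("instance", "batch", "none"), slope = 0.01,
                       down = c("conv", "pool"), classifier = FALSE) {
  kind <- match.arg(kind)
  norm <- match.arg(norm)
  down <- match.arg(down)
  k <- if (kind == "unet2d") c(3L, 3L, 1L) else c(3L, 3L, 3L)
  f <- if (kind == "unet2d") c(2L, 2L, 1L) else c(2L, 2L, 2L)
  structure(list(kind = kind, in_channels = as.integer(in_channels),
                 out_classes = as.integer(out_classes), depth = as.integer(depth),
                 base = as.integer(base_channels), norm = norm, slope = slope,
                 down = down, classifier = isTRUE(classifier),
                 kernel = k, pool = f), class = "net_config")
}

#' Anatomical-network configuration (nnU-Net-style defaults)
#' @param ... overrides passed to [net_config()].
#' @export
anatomical_config <- function(...) {
  args <- list(kind = "unet2d", in_channels = 1L, out_classes = 3L,
               norm = "instance", slope = 0.01, down = "conv")
  args[names(list(...))] <- list(...)
  do.call(net_config, args)
}

#' Pathological-network configuration (3D U-Net with BN/ReLU/max-pool)
#' @param ... overrides passed to [net_config()].
#' @export
pathological_config <- function(...) {
  args <- list(kind = "unet3d", in_channels = 2L, out_classes = 4L,
               norm = "batch", slope = 0, down = "pool", classifier = TRUE)
  args[names(list(...))] <- list(...)
  do.call(net_config, args)
}

#' Build a segmentation network
#'
#' Instantiates the encoder-decoder with freshly initialised weights
#' (He-normal). The returned object holds the parameters, the configuration
#' and any batch-norm running statistics.
#'
#' @param cfg a `net_config`.
#' @param seed RNG seed for the initialisation.
#' @return object of class `lge_net`.
#' @export
build_net <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  set.seed(seed)
  D <- cfg$depth
  ch <- cfg$base * 2L^(0:D)
  k <- cfg$kernel
  pr <- list(enc = vector("list", D + 1L), down = vector("list", D),
             up = vector("list", D), cat_a = vector("list", D),
             cat_b = vector("list", D))
  for (l in seq_len(D + 1L)) {
    cin <- if (l == 1L) cfg$in_channels else if (cfg$down == "conv") ch[l] else ch[l - 1L]
    pr$enc[[l]] <- list(a = conv_params(cin, ch[l], k, cfg$norm),
                        b = conv_params(ch[l], ch[l], k, cfg$norm))
  }
  if (cfg$down == "conv") {
    for (l in seq_len(D)) pr$down[[l]] <- conv_params(ch[l], ch[l + 1L], k, cfg$norm)
  }
  for (l in seq_len(D)) {
    pr$up[[l]] <- conv_params(ch[l + 1L], ch[l], k, cfg$norm)
    pr$cat_a[[l]] <- conv_params(2L * ch[l], ch[l], k, cfg$norm)
    pr$cat_b[[l]] <- conv_params(ch[l], ch[l], k, cfg$norm)
  }
  pr$out <- conv_params(ch[1], cfg$out_classes, c(1L, 1L, 1L), "none")
  if (cfg$classifier) {
    pr$cls <- list(W = matrix(rnorm(2L * ch[D + 1L], sd = sqrt(2 / ch[D + 1L])), nrow = 2L),
                   b = numeric(2L))
  }
  structure(list(cfg = cfg, params = pr, bn = list()), class = "lge_net")
}

#' @export
print.lge_net <- function(x, ...) {
  np <- sum(unlist(rapply(x$params, length, how = "unlist")))
  cat(sprintf("<lge_net> %s depth %d base %d norm %s down %s  (%d parameters)\n",
              x$cfg$kind, x$cfg$depth, x$cfg$base, x$cfg$norm, x$cfg$down, np))
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param net an `lge_net` or CVAE model.
#' @export
n_params <- function(net) sum(unlist(rapply(net$params, length, how = "unlist")))

check_input_shape <- function(cfg, d) {
  need <- cfg$pool^cfg$depth
  if (any(d[2:4] %% need != 0L))
    stop(sprintf(
      "input shape %s not divisible by %s; pad to multiples of (%s)",
      paste(d[2:4], collapse = "x"), paste(need, collapse = "x"),
      paste(need, collapse = ", ")))
  if (d[1] != cfg$in_channels)
    stop(sprintf("expected %d input channels, got %d", cfg$in_channels, d[1]))
}

same_pad <- function(k) as.integer((k - 1L) %/% 2L)

# Forward pass over a batch (list of (C,X,Y,Z) arrays).  Returns softmax
# probability maps, optional classifier scores, updated batch-norm state and
# (when train = TRUE) the caches needed by unet_backward().
unet_forward <- function(net, xs, train = FALSE) {
  cfg <- net$cfg
  for (x in xs) check_input_shape(cfg, dim(x))
  D <- cfg$depth
  k <- cfg$kernel; p1 <- same_pad(k); f <- cfg$pool
  bn <- net$bn
  cache <- list(enc = vector("list", D + 1L), down = vector("list", D),
                up = vector("list", D), cat_a = vector("list", D),
                cat_b = vector("list", D))
  skips <- vector("list", D)
  h <- xs
  for (l in seq_len(D + 1L)) {
    if (l > 1L) {
      if (cfg$down == "conv") {
        id <- paste0("down", l - 1L)
        bl <- block_fwd(net$params$down[[l - 1L]], h, k, f, p1, cfg$norm,
                        cfg$slope, train, bn[[id]])
        bn[[id]] <- bl$bn
        cache$down[[l - 1L]] <- bl$cache
        h <- bl$ys
      } else {
        pool <- lapply(h, function(a) nn_pool_fwd(a, dim(a), f))
        cache$down[[l - 1L]] <- list(idx = lapply(pool, `[[`, "idx"),
                                     xds = lapply(h, dim))
        h <- lapply(pool, `[[`, "y")
      }
    }
    cc <- list()
    for (sub in c("a", "b")) {
      id <- paste0("e", l, sub)
      bl <- block_fwd(net$params$enc[[l]][[sub]], h, k, c(1L, 1L, 1L), p1,
                      cfg$norm, cfg$slope, train, bn[[id]])
      bn[[id]] <- bl$bn
      cc[[sub]] <- bl$cache
      h <- bl$ys
    }
    cache$enc[[l]] <- cc
    if (l <= D) skips[[l]] <- h
  }
  bottleneck <- h
  cls_scores <- NULL
  if (cfg$classifier && !is.null(net$params$cls)) {
    cls_scores <- lapply(h, function(a) {
      v <- rowMeans(mview(a))
      as.vector(net$params$cls$W %*% v + net$params$cls$b)
    })
    cache$gap <- lapply(h, function(a) rowMeans(mview(a)))
  }
  for (l in rev(seq_len(D))) {
    hu <- lapply(h, function(a) nn_upsample_fwd(a, dim(a), f))
    cache$up_dims <- c(cache$up_dims, list(lapply(h, dim)))
    id <- paste0("u", l)
    bl <- block_fwd(net$params$up[[l]], hu, k, c(1L, 1L, 1L), p1, cfg$norm,
                    cfg$slope, train, bn[[id]])
    bn[[id]] <- bl$bn
    cache$up[[l]] <- bl$cache
    h <- mapply(cat_channels, skips[[l]], bl$ys, SIMPLIFY = FALSE)
    for (sub in c("a", "b")) {
      id <- paste0("c", l, sub)
      prm <- if (sub == "a") net$params$cat_a[[l]] else net$params$cat_b[[l]]
      bl <- block_fwd(prm, h, k, c(1L, 1L, 1L), p1, cfg$norm, cfg$slope,
                      train, bn[[id]])
      bn[[id]] <- bl$bn
      if (sub == "a") cache$cat_a[[l]] <- bl$cache else cache$cat_b[[l]] <- bl$cache
      h <- bl$ys
    }
  }
  cache$out_xs <- h
  logits <- lapply(h, function(a)
    nn_conv_fwd(a, dim(a), net$params$out$W, net$params$out$b,
                c(1L, 1L, 1L), c(1L, 1L, 1L), c(0L, 0L, 0L)))
  probs <- lapply(logits, softmax_channels)
  list(probs = probs, logits = logits, cls_scores = cls_scores,
       bottleneck = bottleneck, cache = if (train) cache else NULL, bn = bn)
}

# Backward pass.  dlogits: list of gradients w.r.t. the output logits;
# dcls: optional list of 2-vectors (classifier-score gradients);
# dbottleneck: optional list of extra gradients injected at the bottleneck.
# Returns gradients with the same structure as net$params.
unet_backward <- function(net, cache, dlogits, dcls = NULL, dbottleneck = NULL) {
  cfg <- net$cfg
  D <- cfg$depth
  k <- cfg$kernel; p1 <- same_pad(k); f <- cfg$pool
  gr <- list(enc = vector("list", D + 1L), down = vector("list", D),
             up = vector("list", D), cat_a = vector("list", D),
             cat_b = vector("list", D))
  B <- length(dlogits)
  dW <- matrix(0, nrow(net$params$out$W), ncol(net$params$out$W))
  db <- numeric(nrow(net$params$out$W))
  dh <- vector("list", B)
  for (i in seq_len(B)) {
    g3 <- nn_conv_bwd(cache$out_xs[[i]], dim(cache$out_xs[[i]]),
                      net$params$out$W, dlogits[[i]],
                      c(1L, 1L, 1L), c(1L, 1L, 1L), c(0L, 0L, 0L))
    dW <- dW + g3$dW; db <- db + g3$db
    dh[[i]] <- g3$dx
  }
  gr$out <- list(W = dW, b = db)
  dskips <- vector("list", D)
  upd_i <- length(cache$up_dims)      # up_dims stored top-down for l = D..1
  for (l in seq_len(D)) {
    bb <- block_bwd(net$params$cat_b[[l]], cache$cat_b[[l]], dh, k,
                    c(1L, 1L, 1L), p1, cfg$norm, cfg$slope)
    gr$cat_b[[l]] <- bb$grads
    ba <- block_bwd(net$params$cat_a[[l]], cache$cat_a[[l]], bb$dxs, k,
                    c(1L, 1L, 1L), p1, cfg$norm, cfg$slope)
    gr$cat_a[[l]] <- ba$grads
    c1 <- length(net$params$cat_b[[l]]$b)   # skip channels at this level
    dskip <- vector("list", B); dup <- vector("list", B)
    for (i in seq_len(B)) {
      sp <- split_channels(ba$dxs[[i]], c1)
      dskip[[i]] <- array(sp[[1]], dim = dim(sp[[1]]))
      dup[[i]] <- array(sp[[2]], dim = dim(sp[[2]]))
    }
    dskips[[l]] <- dskip
    bu <- block_bwd(net$params$up[[l]], cache$up[[l]], dup, k,
                    c(1L, 1L, 1L), p1, cfg$norm, cfg$slope)
    gr$up[[l]] <- bu$grads
    lower_dims <- cache$up_dims[[upd_i - l + 1L]]
    dh <- mapply(function(dy, d0) nn_upsample_bwd(dy, dim(dy), f),
                 bu$dxs, lower_dims, SIMPLIFY = FALSE)
  }
  # dh now holds the gradient at the bottleneck output
  if (!is.null(dcls)) {
    W <- net$params$cls$W
    dWc <- matrix(0, nrow(W), ncol(W)); dbc <- numeric(nrow(W))
    for (i in seq_len(B)) {
      v <- cache$gap[[i]]
      ds <- dcls[[i]]
      dWc <- dWc + ds %*% t(v); dbc <- dbc + ds
      dv <- as.vector(t(W) %*% ds)
      d <- dim(dh[[i]])
      n <- prod(d[-1])
      dh[[i]] <- dh[[i]] + array(rep(dv / n, n), dim = d)
    }
    gr$cls <- list(W = dWc, b = dbc)
  }
  if (!is.null(dbottleneck)) {
    for (i in seq_len(B)) dh[[i]] <- dh[[i]] + dbottleneck[[i]]
  }
  for (l in rev(seq_len(D + 1L))) {
    if (l <= D) dh <- mapply(`+`, dh, dskips[[l]], SIMPLIFY = FALSE)
    bb <- block_bwd(net$params$enc[[l]]$b, cache$enc[[l]]$b, dh, k,
                    c(1L, 1L, 1L), p1, cfg$norm, cfg$slope)
    ba <- block_bwd(net$params$enc[[l]]$a, cache$enc[[l]]$a, bb$dxs, k,
                    c(1L, 1L, 1L), p1, cfg$norm, cfg$slope)
    gr$enc[[l]] <- list(a = ba$grads, b = bb$grads)
    dh <- ba$dxs
    if (l > 1L) {
      if (cfg$down == "conv") {
        bd <- block_bwd(net$params$down[[l - 1L]], cache$down[[l - 1L]], dh, k,
                        f, p1, cfg$norm, cfg$slope)
        gr$down[[l - 1L]] <- bd$grads
        dh <- bd$dxs
      } else {
        dc <- cache$down[[l - 1L]]
        dh <- mapply(function(dy, idx, xd) nn_pool_bwd(dy, idx, xd),
                     dh, dc$idx, dc$xds, SIMPLIFY = FALSE)
      }
    }
  }
  list(grads = gr, dxs = dh)
}

# Sliding-window prediction with overlap averaging; window = NULL runs the
# whole grid in one pass.  x is a (C,X,Y,Z) array; returns a probability map.
unet_predict <- function(net, x, window = NULL, stride = NULL) {
  if (is.null(window) || all(window == dim(x)[2:4])) {
    return(unet_forward(net, list(x), train = FALSE)$probs[[1]])
  }
  d <- dim(x)[2:4]
  if (is.null(stride)) stride <- pmax(window %/% 2L, 1L)
  starts <- function(n, w, s) {
    if (w >= n) return(0L)
    v <- unique(c(seq(0L, n - w, by = s), n - w))
    as.integer(v)
  }
  sx <- starts(d[1], window[1], stride[1])
  sy <- starts(d[2], window[2], stride[2])
  sz <- starts(d[3], window[3], stride[3])
  acc <- array(0, dim = c(net$cfg$out_classes, d))
  cnt <- array(0, dim = d)
  for (ox in sx) for (oy in sy) for (oz in sz) {
    xi <- ox + seq_len(window[1]); yi <- oy + seq_len(window[2])
    zi <- oz + seq_len(window[3])
    sub <- x[, xi, yi, zi, drop = FALSE]
    pr <- unet_forward(net, list(sub), train = FALSE)$probs[[1]]
    acc[, xi, yi, zi] <- acc[, xi, yi, zi] + pr
    cnt[xi, yi, zi] <- cnt[xi, yi, zi] + 1
  }
  K <- net$cfg$out_classes
  acc / rep(as.vector(cnt), each = K)
}
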