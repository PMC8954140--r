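# Layer primitives for the CPU conv-net engine.  All tensors are channel-first
# arrays (C, X, Y, Z); batches are lists of such arrays.  Backward passes are
# hand-derived; a finite-difference test pins them down.

mview <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1], prod(d[-1]))
  a
}

conv_params <- function(cin, cout, k, norm = "none") {
  fan_in <- cin * prod(k)
  p <- list(W = matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), nrow = cout),
            b = numeric(cout))
  if (norm != "none") {
    p$g <- rep(1, cout)
    p$be <- numeric(cout)
  }
  p
}

# -- normalisation ----------------------------------------------------------

norm_fwd_stats <- function(M, g, be, eps = 1e-5) {
  mu <- rowMeans(M)
  xc <- M - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  list(y = xhat * g + be, xhat = xhat, istd = istd, mu = mu, v = v)
}

norm_bwd_stats <- function(dY, xhat, istd, g) {
  dg <- rowSums(dY * xhat)
  dbe <- rowSums(dY)
  dxh <- dY * g
  dx <- istd * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
  list(dx = dx, dg = dg, dbe = dbe)
}

# -- conv + norm + activation block over a batch ----------------------------
# norm: "none" | "instance" | "batch"; slope: leaky-ReLU slope (0 = ReLU).
# bn holds running stats for batch norm: list(rm, rv).

block_fwd <- function(bp, xs, k, s, p, norm, slope, train = TRUE, bn = NULL,
                      momentum = 0.1, eps = 1e-5) {
  B <- length(xs)
  ys <- vector("list", B)
  xds <- vector("list", B)
  for (i in seq_len(B)) {
    xds[[i]] <- dim(xs[[i]])
    ys[[i]] <- nn_conv_fwd(xs[[i]], dim(xs[[i]]), bp$W, bp$b, k, s, p)
  }
  cache <- list(xs = xs, xds = xds, yds = lapply(ys, dim))
  if (norm == "instance") {
    ncaches <- vector("list", B)
    for (i in seq_len(B)) {
      d <- dim(ys[[i]])
      st <- norm_fwd_stats(mview(ys[[i]]), bp$g, bp$be, eps)
      ys[[i]] <- array(st$y, dim = d)
      ncaches[[i]] <- st[c("xhat", "istd")]
    }
    cache$ncaches <- ncaches
  } else if (norm == "batch") {
    C <- nrow(bp$W)
    if (is.null(bn)) bn <- list(rm = numeric(C), rv = rep(1, C))
    M <- do.call(cbind, lapply(ys, mview))
    if (train) {
      st <- norm_fwd_stats(M, bp$g, bp$be, eps)
      bn$rm <- (1 - momentum) * bn$rm + momentum * st$mu
      bn$rv <- (1 - momentum) * bn$rv + momentum * st$v
      Yn <- st$y
      cache$ncaches <- st[c("xhat", "istd")]
    } else {
      istd <- 1 / sqrt(bn$rv + eps)
      Yn <- (M - bn$rm) * istd * bp$g + bp$be
    }
    off <- 0L
    for (i in seq_len(B)) {
      n <- prod(dim(ys[[i]])[-1])
      ys[[i]] <- array(Yn[, off + seq_len(n)], dim = dim(ys[[i]]))
      off <- off + n
    }
  }
  amasks <- vector("list", B)
  for (i in seq_len(B)) {
    pos <- ys[[i]] > 0
    amasks[[i]] <- pos
    ys[[i]] <- ys[[i]] * (pos + slope * !pos)
  }
  cache$amasks <- amasks
  list(ys = ys, cache = cache, bn = bn)
}

block_bwd <- function(bp, cache, dys, k, s, p, norm, slope) {
  B <- length(dys)
  for (i in seq_len(B)) {
    m <- cache$amasks[[i]]
    dys[[i]] <- dys[[i]] * (m + slope * !m)
  }
  dg <- dbe <- NULL
  if (norm == "instance") {
    dg <- numeric(length(bp$g)); dbe <- numeric(length(bp$be))
    for (i in seq_len(B)) {
      d <- dim(dys[[i]])
      nb <- norm_bwd_stats(mview(dys[[i]]), cache$ncaches[[i]]$xhat,
                           cache$ncaches[[i]]$istd, bp$g)
      dys[[i]] <- array(nb$dx, dim = d)
      dg <- dg + nb$dg; dbe <- dbe + nb$dbe
    }
  } else if (norm == "batch") {
    M <- do.call(cbind, lapply(dys, mview))
    nb <- norm_bwd_stats(M, cache$ncaches$xhat, cache$ncaches$istd, bp$g)
    dg <- nb$dg; dbe <- nb$dbe
    off <- 0L
    for (i in seq_len(B)) {
      n <- prod(dim(dys[[i]])[-1])
      dys[[i]] <- array(nb$dx[, off + seq_len(n)], dim = dim(dys[[i]]))
      off <- off + n
    }
  }
  dW <- matrix(0, nrow(bp$W), ncol(bp$W))
  db <- numeric(nrow(bp$W))
  dxs <- vector("list", B)
  for (i in seq_len(B)) {
    g3 <- nn_conv_bwd(cache$xs[[i]], cache$xds[[i]], bp$W, dys[[i]], k, s, p)
    dW <- dW + g3$dW; db <- db + g3$db
    dxs[[i]] <- g3$dx
  }
  grads <- list(W = dW, b = db)
  if (!is.null(dg)) { grads$g <- dg; grads$be <- dbe }
  list(dxs = dxs, grads = grads)
}

# -- softmax over the channel dimension -------------------------------------

softmax_channels <- function(logits) {
  d <- dim(logits)
  M <- mview(logits)
  C <- d[1]
  mx <- M[1, ]
  if (C > 1) for (i in 2:C) mx <- pmax(mx, M[i, ])
  E <- exp(M - rep(mx, each = C))
  P <- E / rep(colSums(E), each = C)
  array(P, dim = d)
}

# chain rule through softmax: dL/dlogits from dL/dP and P
softmax_chain <- function(P, dLdP) {
  d <- dim(P)
  Pm <- mview(P); Dm <- mview(dLdP)
  s <- colSums(Pm * Dm)
  array(Pm * (Dm - rep(s, each = d[1])), dim = d)
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[-1]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

split_channels <- function(a, c1) {
  d <- dim(a)
  list(a[seq_len(c1), , , , drop = FALSE],
       a[(c1 + 1L):d[1], , , , drop = FALSE])
}
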