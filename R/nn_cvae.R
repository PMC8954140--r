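# Convolutional variational autoencoder over one-hot cardiac shape volumes.
# Encoder: `stages` strided 3x3x3 convolutions (instance norm, leaky ReLU),
# then dense heads for the latent mean and log-variance.  Decoder mirrors with
# nearest-neighbour upsampling and ends in a softmax over the shape classes.
# A frozen, pretrained instance provides the inclusion-constraint signal: the
# reconstructions of a prediction and of the ground truth are compared in
# Frobenius norm.

#' CVAE configuration
#'
#' @param input_shape spatial grid (rows, cols, slices); must be divisible by
#'   `2^stages` per axis.
#' @param in_channels number of shape classes (one-hot channels).
#' @param base_channels encoder channels at the first stage (doubled per stage).
#' @param latent latent dimension.
#' @param stages number of stride-2 downsampling stages. Two stages keep a
#'   small spatial bottleneck, which the thin scar/MVO structures need for
#'   faithful reconstruction.
#' @param kl_weight weight of the KL term during pretraining; kept small so
#'   the prior regularises without blurring the shape code.
#' @return a `cvae_config` list.
#' @export
cvae_config <- function(input_shape, in_channels = 4L, base_channels = 8L,
                        latent = 64L, stages = 2L, kl_weight = 1e-5) {
  input_shape <- as.integer(input_shape)
  if (any(input_shape %% 2L^stages != 0L))
    stop("input_shape must be divisible by 2^stages per axis")
  structure(list(input_shape = input_shape, in_channels = as.integer(in_channels),
                 base = as.integer(base_channels), latent = as.integer(latent),
                 stages = as.integer(stages), kl_weight = kl_weight),
            class = "cvae_config")
}

#' Build a CVAE shape model
#' @param cfg a [cvae_config()].
#' @param seed RNG seed for initialisation.
#' @return object of class `lge_cvae`.
#' @export
build_cvae <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "cvae_config"))
  set.seed(seed)
  S <- cfg$stages
  ch <- cfg$base * 2L^(0:(S - 1L))
  k <- c(3L, 3L, 3L)
  pr <- list(enc = vector("list", S), dec = vector("list", S))
  for (i in seq_len(S)) {
    cin <- if (i == 1L) cfg$in_channels else ch[i - 1L]
    pr$enc[[i]] <- conv_params(cin, ch[i], k, "instance")
  }
  bshape <- cfg$input_shape %/% 2L^S
  nflat <- ch[S] * prod(bshape)
  pr$mu <- list(W = matrix(rnorm(cfg$latent * nflat, sd = sqrt(1 / nflat)),
                           nrow = cfg$latent), b = numeric(cfg$latent))
  pr$lv <- list(W = matrix(rnorm(cfg$latent * nflat, sd = sqrt(1 / nflat)),
                           nrow = cfg$latent), b = numeric(cfg$latent))
  pr$d0 <- list(W = matrix(rnorm(nflat * cfg$latent, sd = sqrt(1 / cfg$latent)),
                           nrow = nflat), b = numeric(nflat))
  for (i in seq_len(S)) {
    cin <- ch[S - i + 1L]
    cout <- if (i == S) ch[1] else ch[S - i]
    pr$dec[[i]] <- conv_params(cin, cout, k, "instance")
  }
  pr$out <- conv_params(ch[1], cfg$in_channels, c(1L, 1L, 1L), "none")
  structure(list(cfg = cfg, params = pr, bshape = bshape, nflat = nflat),
            class = "lge_cvae")
}

#' @export
print.lge_cvae <- function(x, ...) {
  cat(sprintf("<lge_cvae> grid %s, %d classes, latent %d, %d stages (%d parameters)\n",
              paste(x$cfg$input_shape, collapse = "x"), x$cfg$in_channels,
              x$cfg$latent, x$cfg$stages, n_params(x)))
  invisible(x)
}

cvae_forward <- function(model, x, sample = FALSE, train = FALSE) {
  cfg <- model$cfg
  k <- c(3L, 3L, 3L); p1 <- c(1L, 1L, 1L); s2 <- c(2L, 2L, 2L)
  S <- cfg$stages
  cache <- list(enc = vector("list", S), dec = vector("list", S))
  h <- list(x)
  for (i in seq_len(S)) {
    bl <- block_fwd(model$params$enc[[i]], h, k, s2, p1, "instance", 0.01, TRUE)
    cache$enc[[i]] <- bl$cache
    h <- bl$ys
  }
  flat <- as.vector(h[[1]])
  mu <- as.vector(model$params$mu$W %*% flat + model$params$mu$b)
  lv <- as.vector(model$params$lv$W %*% flat + model$params$lv$b)
  lv <- pmin(pmax(lv, -10), 10)
  epsv <- if (sample) rnorm(length(mu)) else numeric(length(mu))
  z <- mu + epsv * exp(lv / 2)
  d0 <- as.vector(model$params$d0$W %*% z + model$params$d0$b)
  h <- list(array(d0, dim = c(cfg$base * 2L^(S - 1L), model$bshape)))
  cache$d0_in <- z
  cache$flat <- flat
  cache$mu <- mu; cache$lv <- lv; cache$epsv <- epsv
  cache$enc_out_dim <- c(cfg$base * 2L^(S - 1L), model$bshape)
  for (i in seq_len(S)) {
    hu <- lapply(h, function(a) nn_upsample_fwd(a, dim(a), c(2L, 2L, 2L)))
    bl <- block_fwd(model$params$dec[[i]], hu, k, c(1L, 1L, 1L), p1,
                    "instance", 0.01, TRUE)
    cache$dec[[i]] <- bl$cache
    h <- bl$ys
  }
  cache$out_x <- h[[1]]
  logits <- nn_conv_fwd(h[[1]], dim(h[[1]]), model$params$out$W,
                        model$params$out$b, c(1L, 1L, 1L), c(1L, 1L, 1L),
                        c(0L, 0L, 0L))
  recon <- softmax_channels(logits)
  list(recon = recon, mu = mu, lv = lv, z = z,
       cache = if (train) cache else NULL)
}

# backward through the decoder and encoder given dL/d(recon logits); returns
# parameter grads and the gradient w.r.t. the input volume
cvae_backward <- function(model, cache, dlogits, dmu_extra = NULL,
                          dlv_extra = NULL) {
  cfg <- model$cfg
  k <- c(3L, 3L, 3L); p1 <- c(1L, 1L, 1L); s2 <- c(2L, 2L, 2L)
  S <- cfg$stages
  gr <- list(enc = vector("list", S), dec = vector("list", S))
  g3 <- nn_conv_bwd(cache$out_x, dim(cache$out_x), model$params$out$W,
                    dlogits, c(1L, 1L, 1L), c(1L, 1L, 1L), c(0L, 0L, 0L))
  gr$out <- list(W = g3$dW, b = g3$db)
  dh <- list(g3$dx)
  for (i in rev(seq_len(S))) {
    bb <- block_bwd(model$params$dec[[i]], cache$dec[[i]], dh, k,
                    c(1L, 1L, 1L), p1, "instance", 0.01)
    gr$dec[[i]] <- bb$grads
    dh <- lapply(bb$dxs, function(dy) nn_upsample_bwd(dy, dim(dy), c(2L, 2L, 2L)))
  }
  dd0 <- as.vector(dh[[1]])
  gr$d0 <- list(W = dd0 %*% t(cache$d0_in), b = dd0)
  dz <- as.vector(t(model$params$d0$W) %*% dd0)
  dmu <- dz
  dlv <- dz * cache$epsv * 0.5 * exp(cache$lv / 2)
  if (!is.null(dmu_extra)) dmu <- dmu + dmu_extra
  if (!is.null(dlv_extra)) dlv <- dlv + dlv_extra
  gr$mu <- list(W = dmu %*% t(cache$flat), b = dmu)
  gr$lv <- list(W = dlv %*% t(cache$flat), b = dlv)
  dflat <- as.vector(t(model$params$mu$W) %*% dmu + t(model$params$lv$W) %*% dlv)
  dh <- list(array(dflat, dim = cache$enc_out_dim))
  for (i in rev(seq_len(S))) {
    bb <- block_bwd(model$params$enc[[i]], cache$enc[[i]], dh, k, s2, p1,
                    "instance", 0.01)
    gr$enc[[i]] <- bb$grads
    dh <- bb$dxs
  }
  gr <- gr[c("enc", "dec", "mu", "lv", "d0", "out")]  # align with params order
  list(grads = gr, dx = dh[[1]])
}

#' Encode and decode a shape volume through the CVAE
#'
#' Runs the reparameterised encoder-decoder. With `sample = FALSE` (the
#' mean-latent mode) the mapping is deterministic; with `sample = TRUE` the
#' latent is drawn with the reparameterisation trick from R's RNG, so results
#' are reproducible under `set.seed()`.
#'
#' @param x 4D array (classes x rows x cols x slices), one-hot or soft.
#' @param model an `lge_cvae`.
#' @param sample draw the latent stochastically?
#' @return list with `recon` (4D array in `[0,1]`, classes summing to 1) and
#'   `latent` (numeric vector).
#' @export
cvae_encode_decode <- function(x, model, sample = FALSE) {
  stopifnot(inherits(model, "lge_cvae"))
  if (!all(dim(x) == c(model$cfg$in_channels, model$cfg$input_shape)))
    stop("input shape does not match the trained CVAE grid")
  fw <- cvae_forward(model, x, sample = sample, train = FALSE)
  list(recon = fw$recon, latent = fw$z)
}

# gradient of || R(p) - R(g) ||_F^2 w.r.t. p, with the CVAE frozen (mean mode)
cvae_inclusion_grad <- function(model, p, g) {
  fp <- cvae_forward(model, p, sample = FALSE, train = TRUE)
  fg <- cvae_forward(model, g, sample = FALSE, train = FALSE)
  diffr <- fp$recon - fg$recon
  loss <- sum(diffr^2)
  dlog <- softmax_chain(fp$recon, 2 * diffr)
  bw <- cvae_backward(model, fp$cache, dlog)
  list(loss = loss, dp = bw$dx)
}
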