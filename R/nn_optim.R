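# Adam optimiser over nested parameter lists (leaves are numeric arrays).

is_leaf <- function(x) is.numeric(x)

map_params <- function(p, f) {
  if (is.null(p)) return(NULL)
  if (is_leaf(p)) return(f(p))
  lapply(p, map_params, f = f)
}

map2_params <- function(p, q, f) {
  if (is.null(p)) return(NULL)
  if (is.null(q)) return(p)        # missing gradient: leave untouched
  if (is_leaf(p)) return(f(p, q))
  out <- vector("list", length(p))
  nms <- names(p)
  names(out) <- nms
  by_name <- !is.null(nms) && !is.null(names(q)) && all(nzchar(nms))
  for (i in seq_along(p)) {
    qi <- if (by_name) q[[nms[i]]] else q[[i]]
    out[i] <- list(map2_params(p[[i]], qi, f))   # keeps NULL slots
  }
  out
}

adam_init <- function(params) {
  list(m = map_params(params, function(x) x * 0),
       v = map_params(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- map2_params(st$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  st$v <- map2_params(st$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  upd <- map2_params(st$m, st$v, function(m, v) (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map2_params(params, upd, function(p, u) p - lr * u)
  list(params = params, st = st)
}

# polynomial learning-rate decay (exponent 0.9, the standard schedule for the
# anatomical training recipe)
poly_lr <- function(lr0, step, max_steps, power = 0.9) {
  lr0 * (1 - (step - 1) / max_steps)^power
}

sum_grads <- function(a, b) {
  if (is.null(a)) return(b)
  map2_params(a, b, `+`)
}

scale_grads <- function(g, s) map_params(g, function(x) x * s)
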