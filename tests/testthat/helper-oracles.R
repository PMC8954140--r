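# Independent brute-force oracles used to pin the metric and fusion
# implementations.  These deliberately use naive per-voxel loops and stay
# independent of the package's vectorised/C++ code paths.

oracle_dsc <- function(p, g, class_set) {
  d <- dim(p)
  np <- ng <- ni <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    a <- p[i, j, k] %in% class_set
    b <- g[i, j, k] %in% class_set
    np <- np + a; ng <- ng + b; ni <- ni + (a && b)
  }
  if (np + ng == 0L) return(1)
  2 * ni / (np + ng)
}

# boundary: voxel in mask with some 6-neighbour outside (or on the border)
oracle_boundary <- function(mask) {
  d <- dim(mask)
  out <- matrix(0, nrow = 0, ncol = 3)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    on_bd <- FALSE
    for (v in nb) {
      if (any(v < 1) || v[1] > d[1] || v[2] > d[2] || v[3] > d[3]) on_bd <- TRUE
      else if (!mask[v[1], v[2], v[3]]) on_bd <- TRUE
    }
    if (on_bd) out <- rbind(out, c(i, j, k))
  }
  out
}

oracle_hausdorff <- function(p, g, class_set, spacing, mode = "symmetric") {
  A <- oracle_boundary(array(p %in% class_set, dim = dim(p)))
  M <- oracle_boundary(array(g %in% class_set, dim = dim(g)))
  if (nrow(A) == 0L || nrow(M) == 0L) return(NA_real_)
  directed <- function(X, Y) {
    worst <- 0
    for (a in seq_len(nrow(X))) {
      best <- Inf
      for (b in seq_len(nrow(Y))) {
        dd <- sqrt(sum(((X[a, ] - Y[b, ]) * spacing)^2))
        if (dd < best) best <- dd
      }
      if (best > worst) worst <- best
    }
    worst
  }
  if (mode == "directed") return(directed(A, M))
  max(directed(A, M), directed(M, A))
}

oracle_vote <- function(member_maps, anatomical, quorum) {
  d <- dim(anatomical)
  out <- anatomical
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    sv <- mv <- 0L
    for (m in member_maps) {
      if (m[i, j, k] == 3L) sv <- sv + 1L
      if (m[i, j, k] == 4L) mv <- mv + 1L
    }
    if (sv + mv >= quorum) out[i, j, k] <- if (sv >= mv) 3L else 4L
  }
  out
}

# 26-connected components by repeated flood fill (plain R)
oracle_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      k <- (v - 1L) %/% (d[1] * d[2]) + 1L
      rem <- (v - 1L) %% (d[1] * d[2])
      j <- rem %/% d[1] + 1L
      i <- rem %% d[1] + 1L
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        ii <- i + dx; jj <- j + dy; kk <- k + dz
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
        w <- ii + d[1] * (jj - 1L) + d[1] * d[2] * (kk - 1L)
        if (mask[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  lab
}

random_label_map <- function(dims, values = 0:4, p = NULL) {
  array(sample(values, prod(dims), replace = TRUE, prob = p), dim = dims)
}
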