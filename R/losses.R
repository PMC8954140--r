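# Losses for the two training stages.  Probability maps and one-hot targets
# are 4D arrays, classes first.  The multi-class Dice loss keeps the negative
# convention (optimum -1); the segmentation loss of the pathological stage is
# 1 - mean soft IoU so that minimisation is well-posed, with the raw overlap
# exposed separately.  All ratio losses carry an epsilon guard because absent
# classes are common in pathology volumes.

LOSS_EPS <- 1e-6

as_class_matrix <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  matrix(x, nrow = d[1])
}

#' Multi-class Dice loss (negative convention)
#'
#' `-(2/|K|) * sum_k [ sum_i u_ik v_ik / (sum_i u_ik + sum_i v_ik + eps) ]`.
#' Equals -1 exactly when `u` is the one-hot truth and every class is
#' present; a class absent from both maps contributes 0.
#'
#' @param u 4D probability map (classes first).
#' @param v 4D one-hot ground truth of the same shape.
#' @param eps smoothing guard.
#' @return scalar in `[-1, 0]`.
#' @export
loss_dice <- function(u, v, eps = LOSS_EPS) {
  U <- as_class_matrix(u); V <- as_class_matrix(v)
  num <- rowSums(U * V)
  den <- rowSums(U) + rowSums(V) + eps
  -(2 / nrow(U)) * sum(num / den)
}

#' Voxel-wise cross-entropy loss
#'
#' Mean over voxels of `-log u` at the true class, with `u` clamped at `eps`.
#'
#' @inheritParams loss_dice
#' @return non-negative scalar.
#' @export
loss_ce <- function(u, v, eps = LOSS_EPS) {
  U <- as_class_matrix(u); V <- as_class_matrix(v)
  -sum(V * log(pmax(U, eps))) / ncol(U)
}

#' Anatomical training loss: cross-entropy plus Dice
#' @inheritParams loss_dice
#' @export
loss_anatomical <- function(u, v, eps = LOSS_EPS) {
  loss_ce(u, v, eps) + loss_dice(u, v, eps)
}

#' Mean soft intersection-over-union overlap
#'
#' `(1/|C|) * sum_c [ sum_i p*p^' / sum_i (p + p^' - p*p^') ]` - the raw
#' overlap, maximised at 1 by a perfect one-hot prediction.
#'
#' @param p 4D probability map.
#' @param pstar 4D one-hot ground truth.
#' @param eps smoothing guard (absent classes contribute 0 overlap).
#' @export
soft_iou_overlap <- function(p, pstar, eps = LOSS_EPS) {
  P <- as_class_matrix(p); G <- as_class_matrix(pstar)
  num <- rowSums(P * G)
  den <- rowSums(P + G - P * G) + eps
  mean(num / den)
}

#' Soft-IoU segmentation loss
#'
#' `1 - ` [soft_iou_overlap()]; 0 at a perfect one-hot prediction.
#' @inheritParams soft_iou_overlap
#' @export
loss_soft_iou <- function(p, pstar, eps = LOSS_EPS) {
  1 - soft_iou_overlap(p, pstar, eps)
}

#' Inclusion-constraint loss
#'
#' Sum over the batch of squared Frobenius norms of the difference between
#' the shape-model reconstruction of the prediction and that of the ground
#' truth.
#'
#' @param rp reconstruction(s) of the prediction: a 4D array or list of them.
#' @param rg reconstruction(s) of the ground truth, same shape(s).
#' @export
loss_inclusion <- function(rp, rg) {
  if (!is.list(rp)) { rp <- list(rp); rg <- list(rg) }
  stopifnot(length(rp) == length(rg))
  s <- 0
  for (i in seq_along(rp)) s <- s + sum((rp[[i]] - rg[[i]])^2)
  s
}

#' Patient-level classification loss
#'
#' Binary cross-entropy on softmaxed 2-class scores; class order is
#' `(normal, infarcted)`.
#'
#' @param scores numeric length-2 raw scores.
#' @param patient_label `"normal"` or `"infarcted"` (or 1/2 index).
#' @param eps probability clamp.
#' @export
loss_class <- function(scores, patient_label, eps = LOSS_EPS) {
  idx <- if (is.character(patient_label)) {
    match(match.arg(patient_label, c("normal", "infarcted")), c("normal", "infarcted"))
  } else as.integer(patient_label)
  q <- exp(scores - max(scores))
  q <- q / sum(q)
  -log(pmax(q[idx], eps))
}

#' Loss-weight pair for the constrained pathological stage
#' @param lambda_ic,lambda_cc non-negative weights of the inclusion and
#'   classification constraints.
#' @export
loss_weights <- function(lambda_ic = 0.01, lambda_cc = 0.01) {
  stopifnot(lambda_ic >= 0, lambda_cc >= 0)
  structure(list(lambda_ic = lambda_ic, lambda_cc = lambda_cc),
            class = "loss_weights")
}

#' Final pathological training loss
#'
#' `loss_soft_iou + lambda_IC * loss_inclusion + lambda_CC * loss_class`.
#' With both weights zero this reduces exactly to the segmentation term.
#'
#' @inheritParams soft_iou_overlap
#' @inheritParams loss_inclusion
#' @inheritParams loss_class
#' @param w a [loss_weights()] pair.
#' @export
loss_final <- function(p, pstar, rp, rg, scores, patient_label, w) {
  stopifnot(inherits(w, "loss_weights"))
  l <- loss_soft_iou(p, pstar)
  if (w$lambda_ic > 0) l <- l + w$lambda_ic * loss_inclusion(rp, rg)
  if (w$lambda_cc > 0) l <- l + w$lambda_cc * loss_class(scores, patient_label)
  l
}

# -- gradients used by the training loops -----------------------------------

# d(loss_ce + loss_dice)/d logits for one sample, given probs P and one-hot V
grad_anatomical_logits <- function(P, V, eps = LOSS_EPS) {
  d <- dim(P)
  Pm <- as_class_matrix(P); Vm <- as_class_matrix(V)
  K <- d[1]; N <- ncol(Pm)
  dce <- -(Vm / pmax(Pm, eps)) / N
  num <- rowSums(Pm * Vm)
  den <- rowSums(Pm) + rowSums(Vm) + eps
  ddice <- -(2 / K) * (Vm * den - num) / den^2
  softmax_chain(P, array(dce + ddice, dim = d))
}

# d loss_soft_iou / dP (before the softmax chain)
grad_iou_probs <- function(P, G, eps = LOSS_EPS) {
  d <- dim(P)
  Pm <- as_class_matrix(P); Gm <- as_class_matrix(G)
  K <- d[1]
  num <- rowSums(Pm * Gm)
  den <- rowSums(Pm + Gm - Pm * Gm) + eps
  array(-(1 / K) * (Gm * den - num * (1 - Gm)) / den^2, dim = d)
}

# d loss_class / d scores
grad_class_scores <- function(scores, patient_label) {
  idx <- if (is.character(patient_label)) {
    match(patient_label, c("normal", "infarcted"))
  } else as.integer(patient_label)
  q <- exp(scores - max(scores)); q <- q / sum(q)
  t <- numeric(2); t[idx] <- 1
  q - t
}
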