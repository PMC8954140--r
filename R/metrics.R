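# Region- and volume-based evaluation: Dice, Hausdorff distance on boundary
# voxels, absolute volume difference and its rate, MVO presence accuracy,
# patient classification metrics and Bland-Altman summaries.  Structures are
# named voxel-class sets: the myocardium is {2,3,4} (pathology is part of the
# wall), MI is {3,4} (MVO is a subclass of MI), MVO is {4}.

class_mask <- function(x, class_set) {
  lab <- label_array(x)
  array(lab %in% class_set, dim = dim(lab))
}

spacing_of <- function(x, spacing) {
  if (!is.null(spacing)) return(as.numeric(spacing))
  if (inherits(x, "lge_labels")) return(x$spacing)
  c(1, 1, 1)
}

#' Dice similarity coefficient
#'
#' `2|P n G| / (|P| + |G|)` over the voxels of a class set, from 0 (mismatch)
#' to 1 (perfect). When the structure is absent from both maps the score is 1
#' (perfect agreement on absence - the convention used for MVO-free cases).
#'
#' @param p,g predicted and ground-truth label maps (same grid).
#' @param class_set class value(s) defining the structure.
#' @export
dsc <- function(p, g, class_set) {
  pm <- class_mask(p, class_set); gm <- class_mask(g, class_set)
  if (!all(dim(pm) == dim(gm))) stop("label grids differ in shape")
  np <- sum(pm); ng <- sum(gm)
  if (np + ng == 0L) return(1)
  2 * sum(pm & gm) / (np + ng)
}

# boundary voxels of a mask: voxels with at least one 6-neighbour outside the
# mask (voxels on the array border count as boundary)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  interior <- mask
  for (ax in 1:3) {
    for (dirn in c(-1L, 1L)) {
      shifted <- array(FALSE, dim = d)
      n <- d[ax]
      idx_to <- if (dirn == 1L) 2:n else 1:(n - 1)
      idx_from <- if (dirn == 1L) 1:(n - 1) else 2:n
      if (ax == 1) shifted[idx_to, , ] <- mask[idx_from, , ]
      if (ax == 2) shifted[, idx_to, ] <- mask[, idx_from, ]
      if (ax == 3) shifted[, , idx_to] <- mask[, , idx_from]
      interior <- interior & shifted
    }
  }
  mask & !interior
}

#' Hausdorff distance between segmentation boundaries (mm)
#'
#' Boundary voxels are extracted by 6-connectivity erosion difference and
#' distances are Euclidean in spacing-scaled coordinates. The directed
#' distance is `max_a min_m ||a - m||`; the symmetric variant (the default
#' reported in challenge practice) is the max of the two directions.
#' An empty mask makes the distance undefined: `NA` is returned.
#'
#' @param p,g label maps on the same grid.
#' @param class_set structure class value(s).
#' @param spacing voxel spacing in mm (from the maps when omitted).
#' @param mode `"symmetric"` or `"directed"` (from `p` to `g`).
#' @export
hausdorff <- function(p, g, class_set, spacing = NULL,
                      mode = c("symmetric", "directed")) {
  mode <- match.arg(mode)
  sp <- spacing_of(p, spacing)
  pm <- class_mask(p, class_set); gm <- class_mask(g, class_set)
  if (!all(dim(pm) == dim(gm))) stop("label grids differ in shape")
  if (!any(pm) || !any(gm)) return(NA_real_)
  A <- which(boundary_voxels(pm), arr.ind = TRUE) %*% diag(sp)
  M <- which(boundary_voxels(gm), arr.ind = TRUE) %*% diag(sp)
  directed <- function(X, Y) {
    d2 <- outer(rowSums(X^2), rep(1, nrow(Y))) +
      outer(rep(1, nrow(X)), rowSums(Y^2)) - 2 * X %*% t(Y)
    sqrt(max(apply(pmax(d2, 0), 1, min)))
  }
  if (mode == "directed") return(directed(A, M))
  max(directed(A, M), directed(M, A))
}

#' Absolute volume difference and its rate
#'
#' `AVD = |V_A - V_M|` in mm^3; `AVDR = 100 * AVD / V_MYO` (percent), where
#' `V_MYO` is the manual myocardium volume (classes 2-4 of the ground truth).
#'
#' @param p,g predicted and manual label maps.
#' @param class_set structure class value(s).
#' @param spacing voxel spacing in mm.
#' @return named numeric `c(avd = , avdr = )`; `avdr` is `NA` when the manual
#'   myocardium is empty.
#' @export
avd_avdr <- function(p, g, class_set, spacing = NULL) {
  sp <- spacing_of(g, spacing)
  va <- sum(class_mask(p, class_set)) * prod(sp)
  vm <- sum(class_mask(g, class_set)) * prod(sp)
  vmyo <- sum(class_mask(g, 2:4)) * prod(sp)
  avd <- abs(va - vm)
  c(avd = avd, avdr = if (vmyo > 0) 100 * avd / vmyo else NA_real_)
}

#' MVO presence accuracy (case or slice level)
#'
#' Fraction (percent) of cases - or of all slices pooled - where the
#' predicted presence of MVO (any class-4 voxel) matches the ground truth.
#'
#' @param preds,gts lists of label maps, pairwise on the same grids.
#' @param level `"case"` or `"slice"`.
#' @return accuracy in percent.
#' @export
mvo_presence_accuracy <- function(preds, gts, level = c("case", "slice")) {
  level <- match.arg(level)
  stopifnot(length(preds) == length(gts))
  if (level == "case") {
    hit <- mapply(function(p, g) {
      any(label_array(p) == LAB_MVO) == any(label_array(g) == LAB_MVO)
    }, preds, gts)
    return(100 * mean(hit))
  }
  tot <- 0L; ok <- 0L
  for (i in seq_along(preds)) {
    pl <- label_array(preds[[i]]); gl <- label_array(gts[[i]])
    for (s in seq_len(dim(pl)[3])) {
      tot <- tot + 1L
      ok <- ok + (any(pl[, , s] == LAB_MVO) == any(gl[, , s] == LAB_MVO))
    }
  }
  100 * ok / tot
}

#' Patient classification metrics
#'
#' Confusion-matrix ratios with `"infarcted"` as the positive class, in
#' percent.
#'
#' @param pred_labels,true_labels character vectors of `"normal"` /
#'   `"infarcted"`.
#' @return named numeric: sensitivity, specificity, precision, accuracy (%);
#'   ratios with empty denominators are `NA`.
#' @export
classification_metrics <- function(pred_labels, true_labels) {
  stopifnot(length(pred_labels) == length(true_labels))
  pos <- "infarcted"
  tp <- sum(pred_labels == pos & true_labels == pos)
  fn <- sum(pred_labels != pos & true_labels == pos)
  tn <- sum(pred_labels != pos & true_labels != pos)
  fp <- sum(pred_labels == pos & true_labels != pos)
  rate <- function(a, b) if (a + b > 0) 100 * a / (a + b) else NA_real_
  c(sensitivity = rate(tp, fn), specificity = rate(tn, fp),
    precision = rate(tp, fp), accuracy = 100 * (tp + tn) / length(pred_labels))
}

#' Bland-Altman agreement summary
#'
#' Bias (mean of predicted minus manual), the 95% limits of agreement
#' (bias +/- 1.96 SD of the differences), and the (average, difference)
#' pairs for plotting.
#'
#' @param vol_pred,vol_manual numeric vectors (e.g. structure volumes, mm^3).
#' @return list with `bias`, `lower`, `upper`, `pairs` (data.frame with
#'   columns `average`, `difference`).
#' @export
bland_altman <- function(vol_pred, vol_manual) {
  stopifnot(length(vol_pred) == length(vol_manual))
  diffs <- vol_pred - vol_manual
  bias <- mean(diffs)
  s <- if (length(diffs) > 1) sd(diffs) else 0
  list(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s,
       pairs = data.frame(average = (vol_pred + vol_manual) / 2,
                          difference = diffs))
}

#' Evaluate a cohort of predictions against ground truth
#'
#' Per-case Dice / Hausdorff / AVD / AVDR for myocardium ({2,3,4}), MI
#' ({3,4}) and MVO ({4}), plus cohort-level MVO presence accuracy and
#' patient classification metrics.
#'
#' @param preds,gts lists of label maps on matching grids.
#' @return list with `per_case` (data.frame), `summary` (structure means),
#'   `mvo_accuracy` (case/slice %), `classification` (named %).
#' @export
evaluate_cohort <- function(preds, gts) {
  stopifnot(length(preds) == length(gts))
  structures <- list(myocardium = 2:4, mi = c(3L, 4L), mvo = 4L)
  rows <- lapply(seq_along(preds), function(i) {
    out <- list(case = i)
    for (nm in names(structures)) {
      cs <- structures[[nm]]
      va <- avd_avdr(preds[[i]], gts[[i]], class_set = cs)
      out[[paste0("dsc_", nm)]] <- dsc(preds[[i]], gts[[i]], class_set = cs)
      out[[paste0("hd_", nm)]] <- hausdorff(preds[[i]], gts[[i]], class_set = cs)
      out[[paste0("avd_", nm)]] <- va[["avd"]]
      out[[paste0("avdr_", nm)]] <- va[["avdr"]]
    }
    as.data.frame(out)
  })
  per_case <- do.call(rbind, rows)
  summary <- colMeans(per_case[, -1, drop = FALSE], na.rm = TRUE)
  pred_cls <- vapply(preds, classify_patient, character(1))
  true_cls <- vapply(gts, classify_patient, character(1))
  list(per_case = per_case, summary = summary,
       mvo_accuracy = c(case = mvo_presence_accuracy(preds, gts, "case"),
                        slice = mvo_presence_accuracy(preds, gts, "slice")),
       classification = classification_metrics(pred_cls, true_cls))
}
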