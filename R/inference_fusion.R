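# Test-time prediction, majority-voting fusion across the lambda ensemble,
# morphological post-processing and patient-level classification.

#' Predict one case with the two-stage pipeline
#'
#' Locates the LV automatically (first-pass anatomical prediction on a
#' centre-cropped input, falling back to the image centre when no cavity is
#' found), pre-processes, runs the anatomical network (classes 0/1/2) and
#' each pathological ensemble member. Members relabel voxels inside the
#' anatomical myocardium among {myocardium, scar, MVO}; their raw (unmasked)
#' maps are kept for diagnostics.
#'
#' @param v an `lge_volume`.
#' @param anatomical trained anatomical `lge_net`.
#' @param members list of pathological members (each `list(net, w)` or an
#'   `lge_net`).
#' @param target preprocessing target grid.
#' @param quorum majority-vote quorum for pathological labels (default 3).
#' @param window optional sliding-window size for pathological inference
#'   (e.g. `c(12,12,12)`); `NULL` runs whole-grid inference.
#' @return a `vote_stack`: list with `member_maps` (masked label maps on the
#'   target grid), `raw_maps`, `anatomical` (label map {0,1,2}), `record`
#'   (geometry), `quorum`.
#' @export
predict_case <- function(v, anatomical, members, target = c(48L, 48L, 8L),
                         quorum = 3L, window = NULL) {
  stopifnot(inherits(v, "lge_volume"))
  if (!length(members)) stop("no pathological members supplied")
  # first pass: centre crop, anatomical prediction, cavity centroid
  pp0 <- preprocess_case(v, centroid = NULL, target = target)
  pr0 <- unet_predict(anatomical, array(pp0$volume$data, c(1L, target)))
  centroid <- tryCatch(locate_lv_centroid(pr0, cavity_class = 1L),
                       lgeseg_cavity_not_found = function(e) NULL)
  if (!is.null(centroid)) {
    # first pass ran on the centre crop; shift back to original coordinates
    centroid <- centroid + pp0$record$crop_offset
    pp <- preprocess_case(v, centroid = centroid, target = target)
  } else {
    pp <- pp0
  }
  x1 <- array(pp$volume$data, c(1L, target))
  anat_probs <- unet_predict(anatomical, x1)
  anat_map <- onehot_decode(anat_probs, classes = 0:2)
  myo <- anat_map == 2L
  x2 <- array(0, dim = c(2L, target))
  x2[1L, , , ] <- pp$volume$data
  x2[2L, , , ] <- myo
  member_maps <- vector("list", length(members))
  raw_maps <- vector("list", length(members))
  for (m in seq_along(members)) {
    net <- if (inherits(members[[m]], "lge_net")) members[[m]] else members[[m]]$net
    probs <- unet_predict(net, x2, window = window)
    raw <- onehot_decode(probs, classes = c(0L, 2L, 3L, 4L))
    raw_maps[[m]] <- raw
    mm <- anat_map
    if (any(myo)) {
      # relabel myocardial voxels by the argmax over (myo, scar, MVO)
      sub <- matrix(probs, nrow = 4L)[2:4, as.vector(myo), drop = FALSE]
      mm[myo] <- c(2L, 3L, 4L)[max.col(t(sub), ties.method = "first")]
    }
    member_maps[[m]] <- mm
  }
  structure(list(member_maps = member_maps, raw_maps = raw_maps,
                 anatomical = anat_map, record = pp$record,
                 quorum = as.integer(quorum)),
            class = "vote_stack")
}

#' Majority-vote fusion of ensemble label maps
#'
#' A voxel is labelled pathological if at least `quorum` members voted any
#' pathological class (scar or MVO, MVO being a subclass of MI); the class is
#' then the plurality among the pathological votes, ties going to scar.
#' Otherwise the anatomical label stands.
#'
#' @param stack a `vote_stack` (or `list(member_maps=, anatomical=)`).
#' @param quorum override of the stack's quorum.
#' @return 3D integer label map.
#' @export
majority_vote <- function(stack, quorum = NULL) {
  members <- stack$member_maps
  if (!length(members)) stop("empty vote stack")
  if (is.null(quorum)) quorum <- stack$quorum
  if (is.null(quorum)) quorum <- 3L
  if (quorum > length(members))
    warning("quorum exceeds member count; no voxel can reach it")
  d <- dim(members[[1]])
  scar_votes <- Reduce(`+`, lapply(members, function(m) m == 3L))
  mvo_votes <- Reduce(`+`, lapply(members, function(m) m == 4L))
  path_votes <- scar_votes + mvo_votes
  out <- stack$anatomical
  hit <- path_votes >= quorum
  cls <- ifelse(scar_votes >= mvo_votes, 3L, 4L)
  out[hit] <- cls[hit]
  array(as.integer(out), dim = d)
}

#' Morphological post-processing of a fused label map
#'
#' For each pathological class: slice-wise 3x3 binary opening (voxels removed
#' by the opening are relabelled to myocardium), then 3D connected-component
#' analysis (26-connectivity) with components smaller than 64 voxels
#' relabelled to myocardium. MVO components with no scar voxel inside or
#' adjacent are relabelled to scar. The operation is idempotent.
#'
#' @param labels `lge_labels` or 3D integer array.
#' @param min_voxels component-size threshold (components with fewer voxels
#'   are removed; a component of exactly `min_voxels` is retained).
#' @param open_kernel in-plane opening kernel size; the 3x3 default matches
#'   the full-resolution (96 x 96) grid, and `1` disables the opening - the
#'   appropriate setting for half-resolution desk grids, where the same
#'   physical regularisation is below one pixel.
#' @return object of the same kind as the input.
#' @export
postprocess <- function(labels, min_voxels = 64L, open_kernel = 3L) {
  lab <- label_array(labels)
  d <- dim(lab)
  brush <- if (open_kernel > 1L) EBImage::makeBrush(open_kernel, shape = "box")
  for (cls in c(LAB_MI, LAB_MVO)) {
    mask <- lab == cls
    if (!any(mask)) next
    if (open_kernel > 1L) {
      opened <- mask
      for (s in seq_len(d[3])) {
        if (!any(mask[, , s])) next
        opened[, , s] <- EBImage::opening(mask[, , s] + 0, brush) > 0.5
      }
      lab[mask & !opened] <- LAB_MYO
    }
    comp <- cc_label_3d(lab == cls, d)
    sizes <- tabulate(comp[comp > 0L])
    small <- which(sizes < min_voxels)
    if (length(small)) lab[comp %in% small] <- LAB_MYO
  }
  mvo <- lab == LAB_MVO
  if (any(mvo)) {
    scar_dil <- dilate26(lab == LAB_MI)
    mc <- cc_label_3d(mvo, d)
    for (id in setdiff(unique(as.vector(mc)), 0L)) {
      inside <- mc == id
      if (!any(inside & scar_dil)) lab[inside] <- LAB_MI
    }
  }
  if (inherits(labels, "lge_labels")) lge_labels(lab, labels$spacing) else lab
}

#' Patient-level classification from a final segmentation
#'
#' A patient is called infarcted iff any scar or MVO voxels survive
#' post-processing.
#'
#' @param labels final (post-processed) label map.
#' @return `"normal"` or `"infarcted"`.
#' @export
classify_patient <- function(labels) {
  lab <- label_array(labels)
  if (any(lab == LAB_MI | lab == LAB_MVO)) "infarcted" else "normal"
}

#' Select the best ensemble subset by training Dice
#'
#' Picks the candidate subset with the highest mean training Dice over the
#' pathological classes; ties go to the smaller ensemble.
#'
#' @param candidates list of member-index subsets.
#' @param scores numeric vector of mean training DSC per candidate.
#' @return the chosen subset (element of `candidates`).
#' @export
select_ensemble <- function(candidates, scores) {
  stopifnot(length(candidates) == length(scores), length(candidates) >= 1L)
  best <- which(scores == max(scores))
  sizes <- lengths(candidates[best])
  candidates[[best[which.min(sizes)]]]
}

# mean training DSC over pathological classes for one candidate subset,
# fusing with the stack's quorum
score_subset <- function(stacks, gts, subset) {
  per_case <- vapply(seq_along(stacks), function(i) {
    st <- stacks[[i]]
    sub <- list(member_maps = st$member_maps[subset],
                anatomical = st$anatomical,
                quorum = min(st$quorum, length(subset)))
    fused <- majority_vote(sub)
    full <- restore_geometry(fused, st$record)
    mean(c(dsc(full, gts[[i]], class_set = c(3L, 4L)),
           dsc(full, gts[[i]], class_set = 4L)))
  }, numeric(1))
  mean(per_case)
}
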