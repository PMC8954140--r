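#' Construct an LGE-MRI volume
#'
#' A volume is a 3D intensity grid (rows x cols x slices) with millimetre
#' voxel spacing and a record of its original geometry, so that predictions
#' made on a cropped/reshaped grid can be placed back exactly.
#'
#' @param data 3D numeric array (rows x cols x slices); must be finite.
#' @param spacing numeric length-3, voxel size (dx, dy, dz) in mm; all > 0.
#' @param origin_shape integer length-3, grid shape before any cropping.
#' @param crop_offset integer length-2, 0-based (row, col) offset of an
#'   applied in-plane crop relative to the original grid (may be negative
#'   when the crop window extended past the image and was zero-padded).
#' @return An object of class `lge_volume`.
#' @export
lge_volume <- function(data, spacing = c(1, 1, 1),
                       origin_shape = dim(data), crop_offset = c(0L, 0L)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (any(!is.finite(data))) stop("volume data contains NaN/Inf")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values (mm)")
  structure(list(data = data, spacing = spacing,
                 origin_shape = as.integer(origin_shape),
                 crop_offset = as.integer(crop_offset)),
            class = "lge_volume")
}

#' @export
print.lge_volume <- function(x, ...) {
  cat(sprintf("<lge_volume> %s  spacing %s mm  range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a label map
#'
#' Integer class grid aligned with an [lge_volume()]. Classes follow the
#' EMIDEC convention: 0 background, 1 LV cavity, 2 LV myocardium, 3 MI scar,
#' 4 MVO.
#'
#' @param labels 3D integer array with values in 0..4.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return An object of class `lge_labels`.
#' @export
lge_labels <- function(labels, spacing = c(1, 1, 1)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), 0:4)
  if (length(bad)) stop("invalid label values: ", paste(sort(bad), collapse = ", "))
  structure(list(labels = labels, spacing = as.numeric(spacing)),
            class = "lge_labels")
}

#' @export
print.lge_labels <- function(x, ...) {
  tab <- table(factor(as.vector(x$labels), levels = 0:4))
  cat(sprintf("<lge_labels> %s  voxels per class [0..4]: %s\n",
              paste(dim(x$labels), collapse = "x"), paste(tab, collapse = ", ")))
  invisible(x)
}

label_array <- function(x) if (inherits(x, "lge_labels")) x$labels else as.array(x)

#' Validate a per-class probability map
#'
#' A probability map is a 4D array (classes x rows x cols x slices) whose
#' class vector sums to 1 at every voxel.
#'
#' @param probs 4D numeric array.
#' @param tol tolerance on the per-voxel sum.
#' @return `probs`, invisibly, after validation.
#' @export
validate_probmap <- function(probs, tol = 1e-5) {
  d <- dim(probs)
  if (length(d) != 4L) stop("probability map must be 4D (classes first)")
  if (any(probs < -tol | probs > 1 + tol)) stop("probabilities outside [0, 1]")
  s <- colSums(matrix(probs, nrow = d[1]))
  if (any(abs(s - 1) > tol)) stop("per-voxel class probabilities do not sum to 1")
  invisible(probs)
}

#' One-hot encode a label grid
#'
#' @param labels 3D integer array (or `lge_labels`).
#' @param classes integer vector of class values mapped to channels, in order.
#' @return 4D binary array (length(classes) x rows x cols x slices).
#' @export
onehot_encode <- function(labels, classes = 0:4) {
  lab <- label_array(labels)
  out <- array(0, dim = c(length(classes), dim(lab)))
  m <- matrix(out, nrow = length(classes))
  v <- as.vector(lab)
  for (i in seq_along(classes)) m[i, v == classes[i]] <- 1
  array(m, dim = dim(out))
}

#' Decode a probability map or one-hot grid to labels
#'
#' @param probs 4D array, classes first.
#' @param classes class values corresponding to channels.
#' @return 3D integer array of class values.
#' @export
onehot_decode <- function(probs, classes = 0:4) {
  d <- dim(probs)
  idx <- max.col(t(matrix(probs, nrow = d[1])), ties.method = "first")
  array(as.integer(classes[idx]), dim = d[-1])
}

label_sibling_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "_gt.nii\\1", path)
}

#' Read an LGE-MRI volume (and optional labels) from NIfTI
#'
#' Reads `path` as the image; if a sibling file named `<base>_gt.nii(.gz)`
#' exists (or `label_path` is given) it is read and validated as a label map.
#'
#' @param path path to a NIfTI file.
#' @param label_path optional explicit label file path.
#' @return list with `volume` (`lge_volume`) and `labels` (`lge_labels` or NULL).
#' @export
read_volume <- function(path, label_path = NULL) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  vol <- lge_volume(array(as.vector(img), dim = dim(img)), spacing = spacing)
  labels <- NULL
  if (is.null(label_path)) {
    cand <- label_sibling_path(path)
    if (cand != path && file.exists(cand)) label_path <- cand
  }
  if (!is.null(label_path)) {
    if (!file.exists(label_path)) stop("cannot read label file: ", label_path)
    lraw <- RNifti::readNifti(label_path)
    larr <- array(round(as.vector(lraw)), dim = dim(lraw))
    bad <- setdiff(unique(as.vector(larr)), 0:4)
    if (length(bad)) stop("label file has values outside 0..4: ",
                          paste(sort(bad), collapse = ", "))
    labels <- lge_labels(larr, spacing = spacing)
  }
  list(volume = vol, labels = labels)
}

#' Write an LGE-MRI volume (and optional labels) to NIfTI
#'
#' Labels are stored as unsigned 8-bit and round-trip bit-exactly through
#' [read_volume()].
#'
#' @param v an `lge_volume`.
#' @param path output path for the image (`.nii` or `.nii.gz`).
#' @param labels optional `lge_labels`; written to `<base>_gt.nii(.gz)`.
#' @return the image path, invisibly.
#' @export
write_volume <- function(v, path, labels = NULL) {
  stopifnot(inherits(v, "lge_volume"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "lge_labels"))
    if (!all(dim(labels$labels) == dim(v$data))) stop("label/image shape mismatch")
    limg <- RNifti::asNifti(labels$labels + 0)
    RNifti::pixdim(limg) <- labels$spacing
    RNifti::writeNifti(limg, label_sibling_path(path), datatype = "uint8")
  }
  invisible(path)
}

fill_holes_3d <- function(mask) {
  d <- dim(mask)
  bg <- cc_label_3d(!mask, d)
  # background components touching the array border are "outside"; the rest
  # are holes and get filled
  border <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                     bg[, , 1], bg[, , d[3]]))
  border <- setdiff(border, 0L)
  mask | (bg > 0L & !(bg %in% border))
}

dilate26 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    sy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    sz <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    out <- out | mask[sx, sy, sz]
  }
  out
}

#' Check the anatomical nesting of a label map
#'
#' Pathology (scar, MVO) must lie within the myocardial region, and MVO must
#' sit inside or against scar. Returns violation counts without modifying the
#' map. The myocardial region is the hole-filled union of the 26-connected
#' components of classes {2,3,4} that contain at least one myocardium voxel;
#' pathology voxels in components without any myocardium are violations.
#'
#' @param labels `lge_labels` or 3D integer array.
#' @return list with `outside_myocardium` (count of class-3/4 voxels outside
#'   the filled myocardial region), `mvo_isolated` (count of MVO voxels in
#'   components with no scar voxel inside or 26-adjacent), and
#'   `mvo_without_scar` (1 if the map has MVO but no scar at all, else 0).
#' @export
check_topology <- function(labels) {
  lab <- label_array(labels)
  d <- dim(lab)
  path_mask <- lab == LAB_MI | lab == LAB_MVO
  u <- lab == LAB_MYO | path_mask
  outside <- 0L
  if (any(path_mask)) {
    comp <- cc_label_3d(u, d)
    with_myo <- setdiff(unique(comp[lab == LAB_MYO]), 0L)
    region <- array(comp > 0L & (comp %in% with_myo), dim = d)
    region <- fill_holes_3d(region)
    outside <- sum(path_mask & !region)
  }
  mvo_isolated <- 0L
  mvo <- lab == LAB_MVO
  if (any(mvo)) {
    scar_dil <- dilate26(lab == LAB_MI)
    mc <- cc_label_3d(mvo, d)
    for (id in setdiff(unique(as.vector(mc)), 0L)) {
      inside <- mc == id
      if (!any(inside & scar_dil)) mvo_isolated <- mvo_isolated + sum(inside)
    }
  }
  list(outside_myocardium = as.integer(outside),
       mvo_isolated = as.integer(mvo_isolated),
       mvo_without_scar = as.integer(any(lab == LAB_MVO) && !any(lab == LAB_MI)))
}

#' Volume of a structure in mm^3
#'
#' @param labels `lge_labels` or 3D integer array.
#' @param class_set class value(s) defining the structure (e.g. `2:4` for the
#'   whole myocardial shell).
#' @param spacing voxel spacing in mm; taken from `labels` when omitted.
#' @return volume in mm^3 (voxel count times dx*dy*dz).
#' @export
structure_volume <- function(labels, class_set, spacing = NULL) {
  lab <- label_array(labels)
  if (is.null(spacing)) {
    if (!inherits(labels, "lge_labels")) stop("spacing required for plain arrays")
    spacing <- labels$spacing
  }
  sum(lab %in% class_set) * prod(spacing)
}
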