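#' Locate the in-plane centroid of the LV cavity
#'
#' Pools cavity voxels over all slices and returns the integer-rounded
#' in-plane centroid, used to centre the automatic crop. Coordinates are
#' 0-based (row, col), matching the crop-offset convention.
#'
#' @param x an `lge_labels` map, a 3D label array, or a 4D probability map
#'   (classes first) whose channel `cavity_class + 1` is the cavity.
#' @param cavity_class label value of the cavity (default 1).
#' @return integer length-2 vector (row, col), 0-based.
#' @export
locate_lv_centroid <- function(x, cavity_class = LAB_CAV) {
  if (is.array(x) && length(dim(x)) == 4L) {
    lab <- onehot_decode(x, classes = seq_len(dim(x)[1]) - 1L)
  } else {
    lab <- label_array(x)
  }
  idx <- which(lab == cavity_class, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop(structure(class = c("lgeseg_cavity_not_found", "error", "condition"),
                   list(message = "cavity-not-found: no cavity voxels in input",
                        call = sys.call(-1))))
  }
  as.integer(round(colMeans(idx[, 1:2, drop = FALSE])) - 1L)
}

#' Crop around a centroid and reshape to a fixed grid
#'
#' Extracts an in-plane window of `target[1] x target[2]` centred on the
#' cavity centroid (zero-padded where the window extends past the image, so
#' the centroid stays centred) and appends all-zero slices up to `target[3]`.
#' The returned record allows [restore_geometry()] to invert the transform
#' exactly.
#'
#' @param v an `lge_volume`.
#' @param centroid 0-based (row, col) centre, e.g. from [locate_lv_centroid()].
#' @param target integer length-3 target shape (rows, cols, slices).
#' @param z_policy what to do when the input has more slices than
#'   `target[3]`: `"error"` (the expected data regime) or `"center"` to keep
#'   the central slices.
#' @return list with `volume` (cropped `lge_volume`) and `record`
#'   (a `preprocess_record` with crop_offset, pad_slices, target_shape,
#'   origin_shape, z_offset).
#' @export
crop_and_reshape <- function(v, centroid, target = c(96L, 96L, 16L),
                             z_policy = c("error", "center")) {
  stopifnot(inherits(v, "lge_volume"))
  z_policy <- match.arg(z_policy)
  target <- as.integer(target)
  if (any(target[1:2] %% 2L != 0L)) stop("in-plane target size must be even")
  d <- dim(v$data)
  r0 <- as.integer(centroid[1]) - target[1] %/% 2L   # 0-based, may be negative
  c0 <- as.integer(centroid[2]) - target[2] %/% 2L
  z0 <- 0L
  nz <- d[3]
  if (nz > target[3]) {
    if (z_policy == "error")
      stop(sprintf("input has %d slices, more than the target %d", nz, target[3]))
    z0 <- (nz - target[3]) %/% 2L
    nz <- target[3]
  }
  out <- array(0, dim = target)
  # overlap of [r0, r0+target) with [0, d) in 0-based coords
  rs <- max(r0, 0L); re <- min(r0 + target[1], d[1])
  cs <- max(c0, 0L); ce <- min(c0 + target[2], d[2])
  if (re > rs && ce > cs) {
    out[(rs - r0 + 1L):(re - r0), (cs - c0 + 1L):(ce - c0), seq_len(nz)] <-
      v$data[(rs + 1L):re, (cs + 1L):ce, z0 + seq_len(nz)]
  }
  rec <- structure(list(crop_offset = c(r0, c0), pad_slices = target[3] - nz,
                        z_offset = z0, target_shape = target,
                        origin_shape = d, spacing = v$spacing),
                   class = "preprocess_record")
  list(volume = lge_volume(out, spacing = v$spacing, origin_shape = d,
                           crop_offset = c(r0, c0)),
       record = rec)
}

#' Contrast-limited adaptive histogram equalisation (slice-wise)
#'
#' Intensities are rescaled to `[0, 1]` and each slice is equalised with
#' CLAHE (`EBImage::clahe`). A constant image is returned as a constant
#' (zero) image. `limit` follows EBImage's convention of a histogram clip
#' factor.
#'
#' @param v an `lge_volume`.
#' @param tile number of contextual tiles per axis (default 4).
#' @param limit contrast-limiting clip factor (default 1.5).
#' @return an `lge_volume` with intensities in `[0, 1]`.
#' @export
enhance_contrast <- function(v, tile = 4L, limit = 1.5) {
  stopifnot(inherits(v, "lge_volume"))
  x <- v$data
  rng <- range(x)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(1, abs(rng[2]))) {
    x[] <- 0
    return(lge_volume(x, v$spacing, v$origin_shape, v$crop_offset))
  }
  x <- (x - rng[1]) / (rng[2] - rng[1])
  for (s in seq_len(dim(x)[3])) {
    x[, , s] <- EBImage::clahe(x[, , s], nx = tile, ny = tile, limit = limit)
  }
  x <- pmin(pmax(x, 0), 1)
  lge_volume(x, v$spacing, v$origin_shape, v$crop_offset)
}

estimate_noise_sigma <- function(x) {
  # robust sigma from first differences along rows (pseudo-residuals)
  dx <- diff(x)
  stats::mad(as.vector(dx)) / sqrt(2)
}

#' Non-local-means denoising (slice-wise)
#'
#' Classical non-local means with Gaussian patch weighting, applied to each
#' short-axis slice. With `h = NULL` the filter strength is tied to a robust
#' estimate of the noise standard deviation; `h = 0` is the identity.
#'
#' @param v an `lge_volume`.
#' @param patch odd patch size (default 5).
#' @param search odd search-window size (default 11).
#' @param h filter strength; `NULL` for `1.2 * sigma_hat`.
#' @return denoised `lge_volume` of identical shape and spacing.
#' @export
denoise <- function(v, patch = 5L, search = 11L, h = NULL) {
  stopifnot(inherits(v, "lge_volume"))
  x <- v$data
  if (is.null(h)) h <- 1.2 * estimate_noise_sigma(x)
  for (s in seq_len(dim(x)[3])) {
    x[, , s] <- nlm_denoise_slice(x[, , s], as.integer(patch),
                                  as.integer(search), h)
  }
  lge_volume(x, v$spacing, v$origin_shape, v$crop_offset)
}

#' Restore a prediction to the original grid
#'
#' Inverts [crop_and_reshape()]: appended slices are dropped and labels are
#' placed back at their original position; voxels outside the crop window
#' are background.
#'
#' @param pred `lge_labels` (or 3D integer array) on the target grid.
#' @param rec the `preprocess_record` from [crop_and_reshape()].
#' @return an `lge_labels` map on the original grid.
#' @export
restore_geometry <- function(pred, rec) {
  stopifnot(inherits(rec, "preprocess_record"))
  lab <- label_array(pred)
  if (!all(dim(lab) == rec$target_shape))
    stop("prediction shape does not match the preprocess record")
  d <- rec$origin_shape
  out <- array(0L, dim = d)
  r0 <- rec$crop_offset[1]; c0 <- rec$crop_offset[2]
  nz <- rec$target_shape[3] - rec$pad_slices
  rs <- max(r0, 0L); re <- min(r0 + rec$target_shape[1], d[1])
  cs <- max(c0, 0L); ce <- min(c0 + rec$target_shape[2], d[2])
  if (re > rs && ce > cs) {
    out[(rs + 1L):re, (cs + 1L):ce, rec$z_offset + seq_len(nz)] <-
      lab[(rs - r0 + 1L):(re - r0), (cs - c0 + 1L):(ce - c0), seq_len(nz)]
  }
  lge_labels(out, spacing = rec$spacing)
}

#' Full pre-processing chain for one volume
#'
#' crop -> reshape -> adaptive equalisation -> non-local-means, in that
#' order, all operating on the cropped grid. Deterministic for fixed
#' parameters.
#'
#' @param v an `lge_volume`.
#' @param centroid 0-based (row, col) crop centre; when `NULL`, the image
#'   centre is used (the fallback when no cavity is available).
#' @param target target grid shape.
#' @param equalize,denoise_h toggles: `equalize = FALSE` skips CLAHE;
#'   `denoise_h = 0` skips denoising, `NULL` uses the noise-tied default.
#' @param tile,limit,patch,search forwarded to [enhance_contrast()] and
#'   [denoise()].
#' @return list with `volume` and `record`.
#' @export
preprocess_case <- function(v, centroid = NULL, target = c(96L, 96L, 16L),
                            equalize = TRUE, denoise_h = NULL,
                            tile = 4L, limit = 1.5, patch = 5L, search = 11L) {
  if (is.null(centroid)) centroid <- as.integer(dim(v$data)[1:2] %/% 2L)
  cr <- crop_and_reshape(v, centroid, target)
  vol <- cr$volume
  if (equalize) vol <- enhance_contrast(vol, tile = tile, limit = limit)
  if (is.null(denoise_h) || denoise_h > 0)
    vol <- denoise(vol, patch = patch, search = search, h = denoise_h)
  list(volume = vol, record = cr$record)
}
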