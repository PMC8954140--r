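# Synthetic short-axis LGE-MRI phantoms: nested cavity/myocardium rings that
# taper toward the apex, hyper-enhanced scar wedges inside the myocardium and
# hypo-enhanced MVO cores inside scar, with Gaussian noise.  The generator
# exists so that every stage of the pipeline can be trained and evaluated
# without any external data; it does not attempt MR physics (no coil bias,
# Rician noise or partial-volume effects).

#' Phantom specification
#'
#' Geometry is in voxels; intensities are normalised units chosen to mimic
#' LGE contrast: bright blood pool, dark myocardium, hyper-enhanced scar and
#' a hypo-enhanced MVO core.
#'
#' @param shape grid (rows, cols, slices); 5-16 slices is the realistic range.
#' @param spacing voxel spacing in mm.
#' @param cavity_radius,myo_thickness base-slice radii in voxels (jittered
#'   slightly per slice).
#' @param pathology `"none"`, `"scar"` or `"scar+mvo"`.
#' @param scar_arc angular extent of the scar wedge in degrees (0, 360).
#' @param transmurality fraction of the wall thickness the scar penetrates,
#'   from the endocardial border outward.
#' @param mvo_fraction approximate fraction of the scar area forming the MVO
#'   core (> 0 only with `"scar+mvo"`).
#' @param intensities named means for `background`, `cavity`, `myocardium`,
#'   `scar`, `mvo`.
#' @param noise_sigma Gaussian noise SD.
#' @param apex_taper radius scale factor reached at the last slice.
#' @param center_jitter max in-plane centre offset as a fraction of the grid.
#' @param seed RNG seed.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 8L), spacing = c(1.5, 1.5, 8.0),
                         cavity_radius = 7, myo_thickness = 5,
                         pathology = c("none", "scar", "scar+mvo"),
                         scar_arc = 90, transmurality = 0.7,
                         mvo_fraction = 0.3,
                         intensities = c(background = 0.1, cavity = 0.9,
                                         myocardium = 0.3, scar = 0.8,
                                         mvo = 0.15),
                         noise_sigma = 0.05, apex_taper = 0.4,
                         center_jitter = 0.1, seed = 1L) {
  pathology <- match.arg(pathology)
  if (pathology != "scar+mvo") mvo_fraction <- 0
  if (pathology == "scar+mvo" && mvo_fraction <= 0)
    stop("mvo_fraction must be > 0 for scar+mvo phantoms")
  if (scar_arc <= 0 || scar_arc >= 360) stop("scar_arc must be in (0, 360)")
  if (cavity_radius <= 0 || myo_thickness <= 0) stop("radii must be positive")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 cavity_radius = cavity_radius, myo_thickness = myo_thickness,
                 pathology = pathology, scar_arc = scar_arc,
                 transmurality = transmurality, mvo_fraction = mvo_fraction,
                 intensities = intensities, noise_sigma = noise_sigma,
                 apex_taper = apex_taper, center_jitter = center_jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one phantom case
#'
#' Builds the label map slice by slice (concentric cavity/myocardium annulus
#' with radii tapering toward the apex; scar as an angular wedge growing from
#' the endocardial border; MVO as an interior sub-wedge of the scar), then
#' renders intensities with Gaussian noise. The ground truth passes
#' [check_topology()] with zero violations by construction.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (`lge_volume`), `labels` (`lge_labels`),
#'   `patient` (`"normal"` or `"infarcted"`), `type`, `spec`.
#' @export
generate_case <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  r_out_base <- spec$cavity_radius + spec$myo_thickness
  if (2 * (r_out_base + 1) > min(d[1:2]) * (1 - spec$center_jitter))
    stop("annulus does not fit the grid: reduce radii or enlarge the grid")
  ctr <- d[1:2] / 2 + runif(2, -1, 1) * spec$center_jitter * d[1:2]
  lab <- array(0L, dim = d)
  theta0 <- runif(1, 0, 2 * pi)
  arc <- spec$scar_arc * pi / 180
  # scar spans a contiguous central block of slices
  z_scar <- if (spec$pathology == "none") integer(0) else {
    n_scar <- max(3L, round(d[3] * 0.6))
    z0 <- sample.int(max(1L, d[3] - n_scar + 1L), 1L)
    z0:min(d[3], z0 + n_scar - 1L)
  }
  rr <- matrix(seq_len(d[1]), d[1], d[2]) - ctr[1]
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - ctr[2]
  dist <- sqrt(rr^2 + cc^2)
  ang <- (atan2(cc, rr) - theta0) %% (2 * pi)
  for (s in seq_len(d[3])) {
    scale <- 1 - (1 - spec$apex_taper) * (s - 1) / max(1L, d[3] - 1L)
    r_cav <- spec$cavity_radius * scale + runif(1, -0.5, 0.5)
    r_out <- r_cav + spec$myo_thickness * scale + runif(1, -0.5, 0.5)
    sl <- array(0L, dim = d[1:2])
    sl[dist < r_cav] <- LAB_CAV
    sl[dist >= r_cav & dist < r_out] <- LAB_MYO
    if (s %in% z_scar) {
      r_scar <- r_cav + spec$transmurality * (r_out - r_cav)
      wedge <- sl == LAB_MYO & ang < arc & dist < r_scar
      sl[wedge] <- LAB_MI
      if (spec$mvo_fraction > 0) {
        # interior sub-wedge: middle band in angle and radius
        f <- sqrt(spec$mvo_fraction)
        a_lo <- arc * (1 - f) / 2; a_hi <- arc * (1 + f) / 2
        r_lo <- r_cav + (1 - f) / 2 * (r_scar - r_cav)
        r_hi <- r_cav + (1 + f) / 2 * (r_scar - r_cav)
        core <- wedge & ang >= a_lo & ang < a_hi & dist >= r_lo & dist < r_hi
        sl[core] <- LAB_MVO
      }
    }
    lab[, , s] <- sl
  }
  means <- spec$intensities[c("background", "cavity", "myocardium", "scar", "mvo")]
  img <- array(means[lab + 1L], dim = d)
  if (spec$noise_sigma > 0) img <- img + rnorm(length(img), sd = spec$noise_sigma)
  type <- c("none" = "healthy", "scar" = "scar", "scar+mvo" = "scar+mvo")[spec$pathology]
  list(volume = lge_volume(img, spacing = spec$spacing),
       labels = lge_labels(lab, spacing = spec$spacing),
       patient = if (spec$pathology == "none") "normal" else "infarcted",
       type = unname(type), spec = spec)
}

#' Generate a stratified phantom cohort
#'
#' Produces `n` cases with the requested counts of healthy, scar-only and
#' scar+MVO cases (default stratification mirrors the published training
#' cohort: 33 / 27 / 40 out of 100), each with randomised geometry,
#' reproducibly under the seed.
#'
#' @param n cohort size.
#' @param stratification integer length-3: counts of (healthy, scar-only,
#'   scar+MVO) cases; must sum to `n`.
#' @param shape,spacing grid passed to each phantom.
#' @param seed RNG seed.
#' @return list of cases as returned by [generate_case()], each with an `$id`;
#'   the cohort carries a `manifest` attribute (data.frame of id, type,
#'   patient label).
#' @export
generate_cohort <- function(n = 100L, stratification = c(33L, 27L, 40L),
                            shape = c(48L, 48L, 8L),
                            spacing = c(1.5, 1.5, 8.0), seed = 1L) {
  stratification <- as.integer(stratification)
  if (sum(stratification) != n)
    stop("stratification must sum to n (got ",
         paste(stratification, collapse = "+"), " != ", n, ")")
  set.seed(seed)
  types <- sample(rep(c("none", "scar", "scar+mvo"), times = stratification))
  case_seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  gscale <- min(shape[1:2]) / 48          # radii drawn relative to the grid
  geom <- data.frame(cav = runif(n, 6.5, 8.5) * gscale,
                     thick = runif(n, 4.5, 6) * gscale,
                     arc = runif(n, 70, 130), trans = runif(n, 0.55, 0.85),
                     mvo = runif(n, 0.2, 0.35))
  cohort <- lapply(seq_len(n), function(i) {
    sp <- phantom_spec(shape = shape, spacing = spacing,
                       cavity_radius = geom$cav[i], myo_thickness = geom$thick[i],
                       pathology = types[i], scar_arc = geom$arc[i],
                       transmurality = geom$trans[i],
                       mvo_fraction = geom$mvo[i], seed = case_seeds[i])
    cs <- generate_case(sp)
    cs$id <- sprintf("case%03d", i)
    cs
  })
  attr(cohort, "manifest") <- data.frame(
    id = vapply(cohort, `[[`, character(1), "id"),
    type = vapply(cohort, `[[`, character(1), "type"),
    patient = vapply(cohort, `[[`, character(1), "patient"))
  cohort
}

#' Write a cohort to a directory as NIfTI + manifest CSV
#'
#' Emits `caseNNN.nii.gz`, `caseNNN_gt.nii.gz` and `manifest.csv`.
#'
#' @param cohort from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cs in cohort) {
    write_volume(cs$volume, file.path(dir, paste0(cs$id, ".nii.gz")),
                 labels = cs$labels)
  }
  write.csv(attr(cohort, "manifest"), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}
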