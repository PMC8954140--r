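# Training orchestration: cross-validated anatomical stage, CVAE pretraining,
# and constrained pathological training over the lambda grid.

#' Training configuration
#'
#' Defaults follow the published recipe (Adam; anatomical learning rate
#' 3e-4 with polynomial decay; pathological learning rate 1e-4; 12^3 patches
#' with batch size 4; five folds). `max_iters` is scalable: the desk-scale
#' profile in [fast_dev_config()] uses a few hundred steps.
#'
#' @param lr_anatomical,lr_pathological,lr_cvae learning rates.
#' @param patch_size pathological patch size, or `NULL` to train on whole
#'   (cropped) volumes.
#' @param patch_batch patches per step in patch mode.
#' @param batch_size samples per step (whole volumes).
#' @param steps_anatomical,steps_pathological,steps_cvae iteration counts.
#' @param folds cross-validation folds (>= 2).
#' @param target preprocessing target grid.
#' @param base_channels,depth network size.
#' @param members number of ensemble members drawn from the lambda grid.
#' @param constraint_every in patch mode, apply the full-volume inclusion and
#'   classification constraints every this many steps.
#' @param seed RNG seed.
#' @export
train_config <- function(lr_anatomical = 3e-4, lr_pathological = 1e-4,
                         lr_cvae = 1e-3, patch_size = NULL, patch_batch = 4L,
                         batch_size = 4L,
                         steps_anatomical = 200000L, steps_pathological = 200000L,
                         steps_cvae = 2000L, folds = 5L,
                         target = c(96L, 96L, 16L), base_channels = 8L,
                         depth = 2L, members = 8L, constraint_every = 5L,
                         seed = 1L) {
  stopifnot(folds >= 2L, lr_anatomical > 0, lr_pathological > 0)
  structure(list(lr_anatomical = lr_anatomical, lr_pathological = lr_pathological,
                 lr_cvae = lr_cvae, patch_size = patch_size,
                 patch_batch = as.integer(patch_batch),
                 batch_size = as.integer(batch_size),
                 steps_anatomical = as.integer(steps_anatomical),
                 steps_pathological = as.integer(steps_pathological),
                 steps_cvae = as.integer(steps_cvae), folds = as.integer(folds),
                 target = as.integer(target),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), members = as.integer(members),
                 constraint_every = as.integer(constraint_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' Small grids (48 x 48 x 8 phantoms), base 8 / depth 2 networks and a few
#' hundred optimisation steps, sized so the whole pipeline trains in minutes
#' on one CPU core.
#'
#' @param ... overrides passed to [train_config()].
#' @export
fast_dev_config <- function(...) {
  args <- list(steps_anatomical = 250L, steps_pathological = 420L,
               steps_cvae = 300L, batch_size = 2L, folds = 5L,
               patch_size = c(12L, 12L, 8L), patch_batch = 4L,
               constraint_every = 10L,
               target = c(48L, 48L, 8L), base_channels = 8L, depth = 2L,
               members = 5L, lr_anatomical = 2e-3, lr_pathological = 1e-3,
               lr_cvae = 2.5e-3)
  args[names(list(...))] <- list(...)
  do.call(train_config, args)
}

#' Stratified k-fold cross-validation splits
#'
#' Shuffles the case sequence and partitions it into `k` folds, stratified by
#' pathology status so each fold sees a similar case mix. Deterministic for a
#' given seed.
#'
#' @param cases list of cases (each may carry a `$type` or `$patient` field
#'   used for stratification) or an integer count.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param strata optional explicit stratification labels.
#' @return list of `k` elements, each `list(train = idx, val = idx)`; the
#'   validation sets partition the cases.
#' @export
make_folds <- function(cases, k = 5L, seed = 1L, strata = NULL) {
  n <- if (is.numeric(cases) && length(cases) == 1L) as.integer(cases) else length(cases)
  if (k > n) stop("more folds than cases")
  if (is.null(strata) && is.list(cases)) {
    strata <- vapply(cases, function(cs) {
      if (!is.null(cs$type)) as.character(cs$type)
      else if (!is.null(cs$patient)) as.character(cs$patient)
      else "all"
    }, character(1))
  }
  if (is.null(strata)) strata <- rep("all", n)
  set.seed(seed)
  fold_of <- integer(n)
  offset <- 0L
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    fold_of[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), val = which(fold_of == f)))
}

#' The ensemble grid of constraint weights
#'
#' Values from 0.01 to 0.5 in steps of 0.07 for both the inclusion and the
#' classification weight; the default roster pairs the two grids position by
#' position (8 members), with the full Cartesian product available.
#'
#' @param start,step,ceiling grid generation parameters.
#' @param cartesian return all pairs instead of the paired diagonal.
#' @return list with `values` (numeric) and `pairs` (data.frame with columns
#'   `lambda_ic`, `lambda_cc`).
#' @export
lambda_grid <- function(start = 1e-2, step = 7e-2, ceiling = 5e-1,
                        cartesian = FALSE) {
  values <- seq(start, ceiling + 1e-12, by = step)
  values <- round(values, 10)
  pairs <- if (cartesian) {
    expand.grid(lambda_ic = values, lambda_cc = values, KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(lambda_ic = values, lambda_cc = values)
  }
  structure(list(values = values, pairs = pairs), class = "lambda_grid")
}

# -- case preparation -------------------------------------------------------

# Turn a raw cohort (phantom cases or read volumes) into training tensors on
# the target grid: intensity channel, anatomical / pathological one-hot
# targets, the ground-truth myocardial mask, and the geometry record.
prepare_cases <- function(cohort, target = c(48L, 48L, 8L), equalize = TRUE,
                          denoise_h = NULL) {
  lapply(cohort, function(cs) {
    centroid <- tryCatch(locate_lv_centroid(cs$labels),
                         lgeseg_cavity_not_found = function(e) NULL)
    pp <- preprocess_case(cs$volume, centroid = centroid, target = target,
                          equalize = equalize, denoise_h = denoise_h)
    lab_crop <- crop_labels(cs$labels, pp$record)
    x <- array(pp$volume$data, dim = c(1L, target))
    anat <- lab_crop$labels
    anat[anat >= 2L] <- 2L
    path4 <- collapse_path_classes(lab_crop$labels)
    list(id = cs$id, x = x,
         y_anat = onehot_encode(anat, classes = 0:2),
         y_path = onehot_encode(path4, classes = 0:3),
         mask_myo = lab_crop$labels >= 2L,
         labels_crop = lab_crop, record = pp$record,
         labels = cs$labels, patient = cs$patient, type = cs$type)
  })
}

# map EMIDEC labels to the pathological class scheme
# (0 other [bg + cavity], 1 myocardium, 2 scar, 3 MVO)
collapse_path_classes <- function(lab) {
  out <- lab
  out[lab <= 1L] <- 0L
  out[lab == 2L] <- 1L
  out[lab == 3L] <- 2L
  out[lab == 4L] <- 3L
  out
}

# crop a label map with the same geometry as crop_and_reshape
crop_labels <- function(labels, rec) {
  v <- lge_volume(labels$labels + 0, spacing = labels$spacing)
  cr <- crop_and_reshape(v, rec$crop_offset + rec$target_shape[1:2] %/% 2L,
                         target = rec$target_shape,
                         z_policy = if (rec$z_offset > 0) "center" else "error")
  lge_labels(round(cr$volume$data), spacing = labels$spacing)
}

# -- generic segmentation fitting ------------------------------------------

fit_segmentation <- function(xs, ys, cfg_net, steps, lr0, batch_size = 2L,
                             seed = 1L, poly_decay = TRUE, trace_every = 10L) {
  net <- build_net(cfg_net, seed = seed)
  st <- adam_init(net$params)
  set.seed(seed + 7L)
  n <- length(xs)
  trace <- numeric(0)
  for (it in seq_len(steps)) {
    ids <- sample.int(n, min(batch_size, n))
    fw <- unet_forward(net, xs[ids], train = TRUE)
    net$bn <- fw$bn
    B <- length(ids)
    dlog <- vector("list", B)
    lval <- 0
    for (i in seq_len(B)) {
      P <- fw$probs[[i]]; V <- ys[[ids[i]]]
      lval <- lval + loss_anatomical(P, V) / B
      dlog[[i]] <- grad_anatomical_logits(P, V) / B
    }
    if (!is.finite(lval))
      stop(sprintf("training diverged at step %d (loss = %g)", it, lval))
    bw <- unet_backward(net, fw$cache, dlog)
    lr <- if (poly_decay) poly_lr(lr0, it, steps) else lr0
    upd <- adam_step(net$params, bw$grads, st, lr)
    net$params <- upd$params; st <- upd$st
    if (it %% trace_every == 0L || it == 1L) trace <- c(trace, lval)
  }
  list(net = net, trace = trace)
}

#' Train the anatomical network with cross-validation
#'
#' Fits one network per fold on the cross-entropy + Dice loss and evaluates
#' the held-out fold with the standard structure metrics (myocardium Dice,
#' absolute volume difference, Hausdorff distance), returning a per-fold
#' table with mean and SD rows.
#'
#' @param cohort list of cases (e.g. from [generate_cohort()]).
#' @param cfg a [train_config()].
#' @return list with `models` (one per fold), `metrics` (data.frame), and
#'   `folds` (the split).
#' @export
train_anatomical <- function(cohort, cfg = fast_dev_config()) {
  prep <- prepare_cases(cohort, target = cfg$target)
  folds <- make_folds(cohort, k = cfg$folds, seed = cfg$seed)
  acfg <- anatomical_config(depth = cfg$depth, base_channels = cfg$base_channels)
  models <- vector("list", length(folds))
  rows <- list()
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; va <- folds[[f]]$val
    fit <- fit_segmentation(lapply(prep[tr], `[[`, "x"),
                            lapply(prep[tr], `[[`, "y_anat"),
                            acfg, steps = cfg$steps_anatomical,
                            lr0 = cfg$lr_anatomical,
                            batch_size = cfg$batch_size,
                            seed = cfg$seed + f)
    models[[f]] <- fit$net
    m <- vapply(va, function(i) {
      pr <- unet_predict(fit$net, prep[[i]]$x)
      pred <- onehot_decode(pr, classes = 0:2)
      full <- restore_geometry(pred, prep[[i]]$record)
      gt <- prep[[i]]$labels
      c(dsc = dsc(full, gt, class_set = 2:4),
        avd = avd_avdr(full, gt, class_set = 2:4)[["avd"]],
        hd = hausdorff(full, gt, class_set = 2:4))
    }, numeric(3))
    rows[[f]] <- data.frame(fold = f, dsc_myo = mean(m["dsc", ]),
                            avd_myo = mean(m["avd", ]),
                            hd_myo = mean(m["hd", ], na.rm = TRUE))
  }
  tab <- do.call(rbind, rows)
  summary_rows <- data.frame(fold = c(NA, NA),
                             dsc_myo = c(mean(tab$dsc_myo), sd(tab$dsc_myo)),
                             avd_myo = c(mean(tab$avd_myo), sd(tab$avd_myo)),
                             hd_myo = c(mean(tab$hd_myo), sd(tab$hd_myo)))
  rownames(summary_rows) <- NULL
  tab <- rbind(tab, summary_rows)
  tab$stat <- c(rep("fold", length(folds)), "mean", "sd")
  list(models = models, metrics = tab, folds = folds)
}

# single-model anatomical fit on all cases (used by the end-to-end pipeline)
fit_anatomical <- function(prep, cfg) {
  acfg <- anatomical_config(depth = cfg$depth, base_channels = cfg$base_channels)
  fit_segmentation(lapply(prep, `[[`, "x"), lapply(prep, `[[`, "y_anat"),
                   acfg, steps = cfg$steps_anatomical, lr0 = cfg$lr_anatomical,
                   batch_size = cfg$batch_size, seed = cfg$seed)$net
}

#' Pretrain the CVAE shape prior
#'
#' Trains the variational autoencoder on one-hot ground-truth shape volumes,
#' then freezes it. The reconstruction term is a class-weighted voxel
#' cross-entropy (weights `1/freq^0.6`, normalised), without which the thin
#' scar and MVO classes - a few percent and a few permille of the voxels -
#' are washed out of the reconstruction. Reports the reconstruction Dice on
#' the training shapes.
#'
#' @param shapes list of 4D one-hot arrays (classes x rows x cols x slices).
#' @param cfg a [train_config()].
#' @param cvae_cfg optional [cvae_config()]; derived from the shapes if NULL.
#' @param weight_exp exponent of the inverse-frequency class weights.
#' @return list with `model`, `recon_dice`, `trace`.
#' @export
pretrain_cvae <- function(shapes, cfg = fast_dev_config(), cvae_cfg = NULL,
                          weight_exp = 0.6) {
  stopifnot(length(shapes) >= 1L)
  d <- dim(shapes[[1]])
  N <- prod(d[2:4])
  if (is.null(cvae_cfg))
    cvae_cfg <- cvae_config(input_shape = d[2:4], in_channels = d[1])
  freq <- Reduce(`+`, lapply(shapes, function(s) rowSums(matrix(s, d[1])))) /
    (length(shapes) * N)
  w <- (1 / pmax(freq, 1e-6))^weight_exp
  w <- w / mean(w)
  model <- build_cvae(cvae_cfg, seed = cfg$seed)
  st <- adam_init(model$params)
  set.seed(cfg$seed + 11L)
  n <- length(shapes)
  trace <- numeric(0)
  bs <- min(4L, n)
  klw <- cvae_cfg$kl_weight
  for (it in seq_len(cfg$steps_cvae)) {
    ids <- sample.int(n, bs)
    gtot <- NULL
    lval <- 0
    for (i in ids) {
      x <- shapes[[i]]
      fw <- cvae_forward(model, x, sample = TRUE, train = TRUE)
      Rm <- pmax(matrix(fw$recon, d[1]), 1e-7)
      recon_ce <- -sum(w * matrix(x, d[1]) * log(Rm)) / N
      kl <- -0.5 * sum(1 + fw$lv - fw$mu^2 - exp(fw$lv))
      lval <- lval + (recon_ce + klw * kl) / bs
      dLdr <- array(-(w * matrix(x, d[1])) / Rm / N, dim = d)
      dlog <- softmax_chain(fw$recon, dLdr)
      bw <- cvae_backward(model, fw$cache, dlog,
                          dmu_extra = klw * fw$mu,
                          dlv_extra = klw * 0.5 * (exp(fw$lv) - 1))
      gtot <- sum_grads(gtot, scale_grads(bw$grads, 1 / bs))
    }
    if (!is.finite(lval)) stop("CVAE training diverged at step ", it)
    upd <- adam_step(model$params, gtot, st, cfg$lr_cvae)
    model$params <- upd$params; st <- upd$st
    if (it %% 10L == 0L || it == 1L) trace <- c(trace, lval)
  }
  list(model = model, recon_dice = reconstruction_dice(model, shapes),
       trace = trace)
}

#' Reconstruction Dice of a CVAE on a set of shapes
#'
#' Mean over shapes of the macro-averaged Dice between the argmax of the
#' mean-latent reconstruction and the input, over classes present in the
#' input.
#'
#' @param model an `lge_cvae`.
#' @param shapes list of one-hot arrays.
#' @export
reconstruction_dice <- function(model, shapes) {
  per_shape <- vapply(shapes, function(x) {
    r <- cvae_encode_decode(x, model, sample = FALSE)$recon
    truth <- onehot_decode(x, classes = seq_len(dim(x)[1]) - 1L)
    pred <- onehot_decode(r, classes = seq_len(dim(x)[1]) - 1L)
    present <- sort(unique(as.vector(truth)))
    mean(vapply(present, function(k) dsc(pred, truth, class_set = k),
                numeric(1)))
  }, numeric(1))
  mean(per_shape)
}

#' Sample a training patch overlapping the myocardial mask
#'
#' Draws a patch window centred on a random myocardium voxel (clamped to the
#' grid), guaranteeing overlap with the mask.
#'
#' @param mask 3D logical myocardial mask.
#' @param size integer length-3 patch size.
#' @return list with `lo` (0-based corner) and `hi` ranges per axis.
#' @export
sample_patch <- function(mask, size = c(12L, 12L, 12L)) {
  d <- dim(mask)
  if (any(size > d)) stop("patch size exceeds the grid")
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty myocardial mask")
  ctr <- idx[sample.int(nrow(idx), 1L), ]
  lo <- pmin(pmax(ctr - size %/% 2L, 1L), d - size + 1L)
  list(lo = as.integer(lo - 1L), hi = as.integer(lo + size - 1L))
}

#' Train one constrained pathological network
#'
#' Minimises the soft-IoU segmentation loss plus the weighted inclusion
#' (frozen-CVAE reconstruction) and classification (patient-level
#' cross-entropy) constraints. By default whole cropped volumes form the
#' batch; with `cfg$patch_size` set, patches overlapping the myocardial mask
#' carry the segmentation loss and the constraints are applied on the full
#' volume every `cfg$constraint_every` steps. The inclusion term is applied
#' per voxel (the Frobenius norm divided by the grid size) so that constraint
#' weights from the published grid are on the scale of the segmentation loss.
#'
#' @param prep prepared cases from `prepare_cases()` (image tensors, one-hot
#'   targets, masks, patient labels).
#' @param masks list of 3D myocardial masks (one per case), e.g. from the
#'   anatomical stage; cases with empty masks are skipped with a warning.
#' @param cvae frozen `lge_cvae` shape model (or NULL when `lambda_ic = 0`).
#' @param w a [loss_weights()] pair.
#' @param cfg a [train_config()].
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return list with `net`, `trace` (loss trajectory), `w`.
#' @export
train_pathological <- function(prep, masks, cvae = NULL, w = loss_weights(),
                               cfg = fast_dev_config(), seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed
  keep <- vapply(masks, function(m) sum(m) > 0L, logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " case(s) with empty myocardium mask skipped")
    prep <- prep[keep]; masks <- masks[keep]
  }
  if (w$lambda_ic > 0 && is.null(cvae)) stop("lambda_ic > 0 requires a CVAE")
  pcfg <- pathological_config(depth = cfg$depth,
                              base_channels = cfg$base_channels,
                              classifier = TRUE)
  net <- build_net(pcfg, seed = seed)
  st <- adam_init(net$params)
  set.seed(seed + 13L)
  n <- length(prep)
  xs <- lapply(seq_len(n), function(i) {
    d <- dim(prep[[i]]$x)[2:4]
    x2 <- array(0, dim = c(2L, d))
    x2[1L, , , ] <- prep[[i]]$x[1L, , , ]
    x2[2L, , , ] <- masks[[i]]
    x2
  })
  ys <- lapply(prep, `[[`, "y_path")
  labs <- vapply(prep, `[[`, character(1), "patient")
  patch_mode <- !is.null(cfg$patch_size)
  ic_scale <- 1 / prod(dim(prep[[1]]$x)[2:4])   # per-voxel normalisation
  trace <- numeric(0)
  for (it in seq_len(cfg$steps_pathological)) {
    constrained <- !patch_mode || (it %% cfg$constraint_every == 0L)
    bs <- if (patch_mode && !constrained) cfg$patch_batch else cfg$batch_size
    ids <- sample.int(n, min(bs, n))
    if (patch_mode && !constrained) {
      bx <- vector("list", length(ids)); by <- vector("list", length(ids))
      for (j in seq_along(ids)) {
        pw <- sample_patch(masks[[ids[j]]], cfg$patch_size)
        rx <- (pw$lo[1] + 1L):pw$hi[1]; ry <- (pw$lo[2] + 1L):pw$hi[2]
        rz <- (pw$lo[3] + 1L):pw$hi[3]
        bx[[j]] <- xs[[ids[j]]][, rx, ry, rz, drop = FALSE]
        by[[j]] <- ys[[ids[j]]][, rx, ry, rz, drop = FALSE]
      }
    } else {
      bx <- xs[ids]; by <- ys[ids]
    }
    fw <- unet_forward(net, bx, train = TRUE)
    net$bn <- fw$bn
    B <- length(ids)
    dlog <- vector("list", B)
    dcls <- NULL
    lval <- 0
    for (i in seq_len(B)) {
      P <- fw$probs[[i]]; G <- by[[i]]
      lval <- lval + loss_soft_iou(P, G) / B
      dLdP <- grad_iou_probs(P, G)
      if (constrained && w$lambda_ic > 0) {
        ic <- cvae_inclusion_grad(cvae, P, G)
        lval <- lval + w$lambda_ic * ic_scale * ic$loss / B
        dLdP <- dLdP + w$lambda_ic * ic_scale * ic$dp
      }
      dlog[[i]] <- softmax_chain(P, dLdP) / B
    }
    if (constrained && w$lambda_cc > 0) {
      dcls <- vector("list", B)
      for (i in seq_len(B)) {
        lval <- lval + w$lambda_cc * loss_class(fw$cls_scores[[i]], labs[ids[i]]) / B
        dcls[[i]] <- w$lambda_cc *
          grad_class_scores(fw$cls_scores[[i]], labs[ids[i]]) / B
      }
    }
    if (!is.finite(lval))
      stop(sprintf("pathological training diverged at step %d", it))
    bw <- unet_backward(net, fw$cache, dlog, dcls = dcls)
    upd <- adam_step(net$params, bw$grads, st, cfg$lr_pathological)
    net$params <- upd$params; st <- upd$st
    if (it %% 10L == 0L || it == 1L) trace <- c(trace, lval)
  }
  list(net = net, trace = trace, w = w)
}
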