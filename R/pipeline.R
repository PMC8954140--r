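# End-to-end desk-scale pipeline: simulate -> train (anatomical, CVAE,
# constrained ensemble) -> predict (fusion + post-processing) -> evaluate.

#' Run the full pipeline on synthetic phantoms
#'
#' Generates stratified training and test cohorts, trains the anatomical
#' network on the training cohort, pretrains the CVAE shape prior on the
#' training ground-truth shapes, trains `cfg$members` pathological networks
#' with constraint weights spread along the lambda grid, and evaluates the
#' fused, post-processed predictions on the held-out test cohort.
#'
#' @param cfg a [train_config()]; [fast_dev_config()] by default.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param n_train,n_test cohort sizes.
#' @param strat_train,strat_test (healthy, scar-only, scar+MVO) counts; the
#'   defaults scale the published 100/50-case stratification down to 30/10.
#' @param quorum majority-vote quorum.
#' @param open_kernel opening kernel for [postprocess()]; by default 3 on
#'   full-resolution (>= 96) grids and 1 (no opening) on smaller desk grids,
#'   keeping the physical scale of the regularisation.
#' @param min_voxels component threshold for [postprocess()]; 64 on
#'   full-resolution grids, scaled by the in-plane area ratio (16 at 48 x 48)
#'   on desk grids whose phantom lesions are proportionally smaller.
#' @return list with the trained models, per-case predictions, the evaluation
#'   report, and the test cohort.
#' @export
run_pipeline <- function(cfg = fast_dev_config(), seed = 1L,
                         n_train = 30L, n_test = 10L,
                         strat_train = c(10L, 8L, 12L),
                         strat_test = c(4L, 4L, 2L), quorum = 3L,
                         open_kernel = NULL, min_voxels = NULL) {
  cfg$seed <- as.integer(seed)
  shape <- cfg$target
  if (is.null(open_kernel)) open_kernel <- if (shape[1] >= 96L) 3L else 1L
  if (is.null(min_voxels))
    min_voxels <- max(1L, as.integer(round(64 * (min(shape[1], 96L) / 96)^2)))
  cohort_tr <- generate_cohort(n_train, strat_train, shape = shape, seed = seed)
  cohort_te <- generate_cohort(n_test, strat_test, shape = shape, seed = seed + 1L)
  prep_tr <- prepare_cases(cohort_tr, target = cfg$target)

  anat <- fit_anatomical(prep_tr, cfg)

  shapes <- lapply(prep_tr, `[[`, "y_path")
  cvae <- pretrain_cvae(shapes, cfg)

  # pre-segmented myocardium from the anatomical stage, per training case
  masks <- lapply(prep_tr, function(pc) {
    pr <- unet_predict(anat, pc$x)
    onehot_decode(pr, classes = 0:2) == 2L
  })

  pairs <- lambda_grid()$pairs
  idx <- unique(round(seq(1L, nrow(pairs), length.out = cfg$members)))
  members <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    w <- loss_weights(pairs$lambda_ic[idx[j]], pairs$lambda_cc[idx[j]])
    members[[j]] <- train_pathological(prep_tr, masks, cvae$model, w, cfg,
                                       seed = seed + 100L + j)
  }

  preds <- vector("list", n_test)
  stacks <- vector("list", n_test)
  for (i in seq_len(n_test)) {
    st <- predict_case(cohort_te[[i]]$volume, anat, members,
                       target = cfg$target, quorum = quorum)
    fused <- majority_vote(st)
    final <- postprocess(fused, min_voxels = min_voxels,
                         open_kernel = open_kernel)
    preds[[i]] <- restore_geometry(final, st$record)
    stacks[[i]] <- st
  }
  gts <- lapply(cohort_te, `[[`, "labels")
  report <- evaluate_cohort(preds, gts)
  topo <- vapply(preds, function(p) check_topology(p)$outside_myocardium,
                 integer(1))
  list(anatomical = anat, cvae = cvae, members = members,
       lambda_pairs = pairs[idx, , drop = FALSE],
       predictions = preds, stacks = stacks, test_cohort = cohort_te,
       report = report, topology_violations = topo,
       classification_accuracy = unname(report$classification["accuracy"]))
}

#' Paired inclusion-constraint ablation
#'
#' Trains two pathological networks from the same seed and cohort, one with
#' `lambda_IC = 0` and one with `lambda_IC > 0` (classification weight held
#' at 0 in both), and counts the raw-network topology violations - pathology
#' voxels predicted outside the myocardial region before any anatomical
#' masking - on held-out cases. Ground-truth myocardial masks are used for
#' both runs so the comparison isolates the inclusion constraint.
#'
#' @param lambda_ic the non-zero inclusion weight (default 0.29, the grid
#'   midpoint).
#' @param cfg a [train_config()].
#' @param seed shared RNG seed for the paired runs.
#' @param n_train,n_test cohort sizes (pathological cases only).
#' @return list with `violations_without`, `violations_with` (total counts),
#'   and the per-case counts.
#' @export
run_ic_ablation <- function(lambda_ic = 0.29,
                            cfg = fast_dev_config(steps_cvae = 200L,
                                                  steps_pathological = 300L),
                            seed = 1L, n_train = 12L, n_test = 4L) {
  cfg$seed <- as.integer(seed)
  shape <- cfg$target
  n_mvo <- n_train %/% 2L
  cohort_tr <- generate_cohort(n_train, c(0L, n_train - n_mvo, n_mvo),
                               shape = shape, seed = seed)
  cohort_te <- generate_cohort(n_test, c(0L, n_test - n_test %/% 2L, n_test %/% 2L),
                               shape = shape, seed = seed + 1L)
  prep_tr <- prepare_cases(cohort_tr, target = cfg$target)
  prep_te <- prepare_cases(cohort_te, target = cfg$target)
  masks_tr <- lapply(prep_tr, `[[`, "mask_myo")

  shapes <- lapply(prep_tr, `[[`, "y_path")
  cvae <- pretrain_cvae(shapes, cfg)

  raw_violations <- function(net) {
    vapply(prep_te, function(pc) {
      x2 <- array(0, dim = c(2L, cfg$target))
      x2[1L, , , ] <- pc$x[1L, , , ]
      x2[2L, , , ] <- pc$mask_myo
      pr <- unet_predict(net, x2)
      raw <- onehot_decode(pr, classes = c(0L, 2L, 3L, 4L))
      check_topology(raw)$outside_myocardium
    }, integer(1))
  }
  fit_without <- train_pathological(prep_tr, masks_tr, cvae$model,
                                    loss_weights(0, 0), cfg, seed = seed + 50L)
  fit_with <- train_pathological(prep_tr, masks_tr, cvae$model,
                                 loss_weights(lambda_ic, 0), cfg,
                                 seed = seed + 50L)
  v0 <- raw_violations(fit_without$net)
  v1 <- raw_violations(fit_with$net)
  list(violations_without = sum(v0), violations_with = sum(v1),
       per_case_without = v0, per_case_with = v1, cvae = cvae)
}
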