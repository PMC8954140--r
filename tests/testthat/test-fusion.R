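mk_stack <- function(member_maps, anatomical, quorum = 3L) {
  structure(list(member_maps = member_maps, anatomical = anatomical,
                 quorum = quorum), class = "vote_stack")
}

test_that("majority vote honours unanimity and the quorum-3 infarct rule", {
  anat <- array(2L, c(4, 4, 2))
  m <- array(2L, c(4, 4, 2)); m[1, 1, 1] <- 3L
  expect_equal(majority_vote(mk_stack(rep(list(m), 5), anat)), m)
  # 8 members: 3 vote scar at one voxel, 5 myocardium -> scar at quorum 3
  base <- array(2L, c(4, 4, 2))
  scar1 <- base; scar1[2, 2, 1] <- 3L
  stack <- mk_stack(c(rep(list(scar1), 3), rep(list(base), 5)), anat)
  fused <- majority_vote(stack)
  expect_equal(fused[2, 2, 1], 3L)
  # only 2 of 8 voting pathological stays anatomical
  stack2 <- mk_stack(c(rep(list(scar1), 2), rep(list(base), 6)), anat)
  expect_equal(majority_vote(stack2)[2, 2, 1], 2L)
  expect_error(majority_vote(mk_stack(list(), anat)), "empty")
})

test_that("plurality among pathological votes breaks ties toward scar", {
  anat <- array(2L, c(2, 2, 1))
  scar <- array(3L, c(2, 2, 1))
  mvo <- array(4L, c(2, 2, 1))
  # 2 scar vs 2 MVO votes: tie -> scar (MVO is a subclass of MI)
  fused <- majority_vote(mk_stack(list(scar, scar, mvo, mvo), anat, quorum = 3L))
  expect_true(all(fused == 3L))
  # 1 scar vs 3 MVO: plurality -> MVO
  fused2 <- majority_vote(mk_stack(list(scar, mvo, mvo, mvo), anat, quorum = 3L))
  expect_true(all(fused2 == 4L))
})

test_that("majority vote matches the counting oracle and ignores member order", {
  set.seed(41)
  for (i in 1:5) {
    anat <- random_label_map(c(12, 12, 3), values = 0:2)
    members <- lapply(1:8, function(m)
      random_label_map(c(12, 12, 3), values = c(0L, 2L, 3L, 4L)))
    fused <- majority_vote(mk_stack(members, anat))
    expect_identical(fused, oracle_vote(members, anat, 3L))
    perm <- sample(8)
    expect_identical(majority_vote(mk_stack(members[perm], anat)), fused)
  }
})

test_that("post-processing enforces the 64-voxel threshold semantics", {
  base <- array(2L, c(20, 20, 4))
  # a compact 4x4x4 block of scar: 64 voxels, retained
  with64 <- base; with64[3:6, 3:6, 1:4] <- 3L
  out64 <- postprocess(with64, open_kernel = 1L)
  expect_equal(sum(out64 == 3L), 64L)
  # remove one voxel -> 63, dropped and relabelled to myocardium
  with63 <- with64; with63[3, 3, 1] <- 2L
  out63 <- postprocess(with63, open_kernel = 1L)
  expect_equal(sum(out63 == 3L), 0L)
  expect_true(all(out63[with63 == 3L] == 2L))
  # all-myocardium map passes through untouched
  expect_identical(postprocess(base), base)
})

test_that("opening removes slice-wise speckle before component analysis", {
  base <- array(2L, c(20, 20, 4))
  speck <- base
  set.seed(2)
  idx <- cbind(sample(1:20, 70, TRUE), sample(1:20, 70, TRUE), sample(1:4, 70, TRUE))
  speck[idx] <- 3L                       # scattered single-voxel scar
  out <- postprocess(speck, open_kernel = 3L)
  expect_equal(sum(out == 3L), 0L)
  # a solid 8x8 per-slice block survives the 3x3 opening
  solid <- base; solid[5:12, 5:12, 1:2] <- 3L
  out2 <- postprocess(solid, open_kernel = 3L)
  expect_equal(sum(out2 == 3L), 128L)
})

test_that("isolated MVO components are converted to scar", {
  base <- array(2L, c(24, 24, 4))
  lab <- base
  lab[3:10, 3:10, 1:4] <- 3L             # scar block (256 voxels)
  lab[15:18, 15:18, 1:4] <- 4L           # MVO block (64) far from scar
  out <- postprocess(lab, open_kernel = 1L)
  expect_equal(sum(out == 4L), 0L)
  expect_equal(sum(out[15:18, 15:18, 1:4] == 3L), 64L)
  # MVO adjacent to scar is kept
  lab2 <- base
  lab2[3:10, 3:10, 1:4] <- 3L
  lab2[5:8, 5:8, 1:4] <- 4L              # nested core
  out2 <- postprocess(lab2, open_kernel = 1L)
  expect_equal(sum(out2 == 4L), 64L)
})

test_that("post-processing is idempotent", {
  set.seed(43)
  # structured fused-like maps: phantom GT with injected speckle
  for (i in 1:4) {
    cs <- generate_case(phantom_spec(pathology = "scar+mvo", seed = i,
                                     shape = c(48L, 48L, 8L)))
    lab <- cs$labels$labels
    idx <- cbind(sample(1:48, 30, TRUE), sample(1:48, 30, TRUE), sample(1:8, 30, TRUE))
    lab[idx] <- sample(c(3L, 4L), 30, TRUE)
    for (kern in c(1L, 3L)) {
      once <- postprocess(lab, open_kernel = kern)
      twice <- postprocess(once, open_kernel = kern)
      expect_identical(twice, once)
    }
  }
})

test_that("3D connected components agree with a flood-fill oracle", {
  set.seed(47)
  for (i in 1:5) {
    mask <- array(runif(10 * 10 * 4) < 0.35, c(10, 10, 4))
    lab <- cc_label_3d(mask, dim(mask))
    ref <- oracle_components(mask)
    # same partition: component census and label-set correspondence
    expect_equal(sort(tabulate(lab[lab > 0])), sort(tabulate(ref[ref > 0])))
    expect_true(all((lab > 0) == mask))
    for (id in setdiff(unique(as.vector(lab)), 0L)) {
      expect_equal(length(unique(ref[lab == id])), 1L)
    }
  }
})

test_that("patient classification reads surviving pathology", {
  base <- array(2L, c(20, 20, 4))
  with64 <- base; with64[3:6, 3:6, 1:4] <- 3L
  expect_equal(classify_patient(postprocess(with64, open_kernel = 1L)), "infarcted")
  expect_equal(classify_patient(base), "normal")
})

test_that("ensemble selection is argmax with ties to the smaller subset", {
  cands <- list(c(1L), c(1L, 2L), c(1L, 2L, 3L))
  expect_equal(select_ensemble(cands[1], 0.7), 1L)
  expect_equal(select_ensemble(cands, c(0.7, 0.8, 0.75)), c(1L, 2L))
  expect_equal(select_ensemble(cands, c(0.8, 0.8, 0.8)), 1L)     # tie -> smallest
  # matches an exhaustive scan over subsets
  set.seed(53)
  scores <- runif(length(cands))
  best <- which.max(scores)
  expect_equal(select_ensemble(cands, scores), cands[[best]])
})

test_that("member predictions stay inside the anatomical myocardium mask", {
  cs <- generate_case(phantom_spec(pathology = "scar", seed = 21,
                                   shape = c(24L, 24L, 8L), cavity_radius = 4,
                                   myo_thickness = 3))
  anat <- build_net(anatomical_config(depth = 1, base_channels = 4), seed = 1)
  members <- lapply(1:3, function(j)
    build_net(pathological_config(depth = 1, base_channels = 4), seed = j))
  st <- predict_case(cs$volume, anat, members, target = c(24L, 24L, 8L))
  myo <- st$anatomical == 2L
  for (mm in st$member_maps) {
    expect_true(all((mm %in% c(3L, 4L)) <= myo))   # pathology only inside mask
    expect_true(all(mm[!myo] == st$anatomical[!myo]))
  }
  # deterministic for fixed weights and input
  st2 <- predict_case(cs$volume, anat, members, target = c(24L, 24L, 8L))
  expect_identical(st$member_maps, st2$member_maps)
})
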