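---
title: "Constrained segmentation of LV myocardial pathology from LGE-MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained segmentation of LV myocardial pathology from LGE-MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Late-gadolinium-enhancement (LGE) cardiac MRI is the reference technique for
delineating myocardial infarction: about ten minutes after contrast
injection, infarcted muscle retains gadolinium and appears hyper-enhanced,
while microvascular obstruction (MVO, the "no-reflow" phenomenon) appears as
a hypo-enhanced core inside the acute infarct. Quantifying the left-ventricle
(LV) cavity, healthy myocardium, scar and MVO from a stack of 5–16 short-axis
slices supports viability assessment and arrhythmia-risk stratification.

Two properties make this segmentation hard. First, class imbalance: the scar
is a few percent of the voxels and MVO a few per mille. Second, anatomy: the
pathological tissues are not free-floating — MVO lies inside scar, scar lies
inside the myocardial wall, and the wall is an annulus around the blood pool.
Plain voxel-wise training ignores those relations and produces anatomically
implausible speckle.

`lgeseg` implements a two-stage pipeline that builds the anatomy in first:

1. **Anatomical stage** — a U-Net (instance normalisation, leaky ReLU with
   slope 0.01, strided-convolution downsampling) segments background, LV
   cavity and myocardium with the sum of cross-entropy and multi-class Dice
   loss, `L = L_CE + L_Dice`, where the Dice term keeps its negative
   convention

   `L_Dice = -(2/|K|) * sum_k [ sum_i u_ik v_ik / (sum_i u_ik + sum_i v_ik + eps) ]`

   (`u` the softmax output, `v` the one-hot truth; optimum exactly −1 when
   every class is present). Training follows five-fold cross-validation with
   Adam and a polynomially decaying learning rate (exponent 0.9).

2. **Pathological stage** — a 3D U-Net (batch normalisation, ReLU,
   max-pooling) relabels the pre-segmented myocardium into healthy wall,
   scar and MVO. It is trained with

   `L_final = L_Seg + lambda_IC * L_IC + lambda_CC * L_CC`

   where `L_Seg` is one minus the mean soft intersection-over-union (the raw
   overlap is exposed as `soft_iou_overlap()`; as an overlap it is maximised
   at a perfect prediction, so the minimised loss is its complement),
   `L_IC` compares the frozen shape-model reconstructions of the prediction
   and of the ground truth in squared Frobenius norm, and `L_CC` is a binary
   (infarcted vs normal patient) cross-entropy on a two-unit head attached to
   the U-Net bottleneck by global average pooling, active only during
   training.

3. **Fusion and post-processing** — one pathological network is trained per
   constraint-weight pair along the grid `lambda ∈ {0.01, 0.08, …, 0.50}`
   (start 0.01, step 0.07); at test time a voxel becomes pathological iff at
   least three ensemble members voted a pathological class, with the class
   decided by plurality (ties to scar, MVO being a subclass of MI).
   Slice-wise 3×3 binary opening and 3D connected-component filtering
   (components under 64 voxels relabelled to myocardium; a 64-voxel
   component is retained) clean the fused map, isolated MVO components are
   converted to scar, and the map is placed back on the original grid.

A patient is classified as infarcted iff any scar or MVO survives
post-processing.

## The shape prior (CVAE)

The inclusion constraint needs a model of what a plausible set of nested
cardiac shapes looks like. A convolutional variational autoencoder is
pretrained on one-hot ground-truth label volumes (channels: other,
myocardium, scar, MVO) and then frozen; during constrained training the
prediction and the ground truth are both passed through it and their
reconstructions compared.

Design choices that mattered in practice:

* **Two stride-2 encoder stages, latent dimension 64.** A deeper encoder
  (three stages, 6×6×1 bottleneck on the desk grid) cannot localise the
  few-voxel MVO cores and plateaus around reconstruction Dice 0.7; keeping a
  12×12×2 spatial bottleneck lifts it above 0.9.
* **KL weight 1e-5.** With larger weights the KL term grows to the magnitude
  of the reconstruction term and blurs the code; the prior is kept as a weak
  regulariser.
* **Class-weighted reconstruction cross-entropy**, weights `1/freq^0.6`
  normalised to mean one. Unweighted training washes the scar and MVO
  channels out of the reconstruction entirely (they are ~1% and ~0.1% of
  voxels).
* **Reconstruction Dice** is reported as the mean over shapes of the
  macro-averaged per-class Dice across classes present in the shape — the
  strictest of the common conventions, chosen because the constraint's whole
  point is the small classes.

The reparameterised latent is sampled during pretraining and fixed to its
mean during constraint evaluation, making the inclusion signal
deterministic.

## Scale of the constraint terms

The inclusion loss as defined (a summed squared Frobenius norm over the
volume) is three orders of magnitude larger than the soft-IoU term, while
the published weight grid spans only 0.01–0.5. Inside the training loop the
constraint is therefore applied per voxel (divided by the grid size), which
puts its gradient on the scale of the segmentation gradient and makes the
grid weights meaningful. The exported `loss_inclusion()` keeps the raw
summed definition.

## Patch training

The pathological network trains on patches sampled to overlap the myocardial
mask (12×12×12 at full scale; 12×12×8 on the 8-slice desk grid), batch 4.
The two constraints need whole-volume context — a CVAE reconstruction of a
patch is meaningless and a patient label does not apply to a patch — so
every tenth step is a whole-volume step carrying the inclusion and
classification terms. A whole-volume-only mode (`patch_size = NULL`)
exists and was used to validate the patch mode against it.

## The synthetic phantom

No clinical data ships with the package; every stage trains and evaluates on
a synthetic short-axis phantom emulating the structure of LGE exams:

* concentric cavity/myocardium annulus per slice, radii tapering linearly to
  40 % toward the apex, with ±0.5-voxel per-slice jitter and a random
  in-plane centre offset (≤10 % of the grid) so the automatic centroid crop
  is actually exercised;
* scar as an angular wedge growing from the endocardial border over a
  contiguous central block of slices (arc 70–130°, transmurality 0.55–0.85
  across a cohort);
* MVO as an interior sub-wedge of the scar (≈20–35 % of its area), nested so
  the ground truth passes `check_topology()` with zero violations by
  construction;
* normalised intensities: background 0.1, myocardium 0.3, scar 0.8
  (hyper-enhanced), MVO 0.15 (hypo-enhanced), cavity 0.9, Gaussian noise
  σ = 0.05 — chosen to mimic LGE contrast ordering; the ordering survives in
  expectation for σ well below the 0.25 class-mean gaps.

Cohorts are stratified (healthy / scar-only / scar+MVO) following the
33/27/40-per-100 mix of the clinical training cohort the pipeline targets,
scaled by largest remainder for other sizes (30 training phantoms: 10/8/12;
10 test phantoms: 4/4/2).

What the phantom does **not** model: MR physics (coil bias fields, Rician
noise, partial-volume effects), papillary muscles, the right ventricle,
respiratory slice misalignment, and the intensity overlap between scar and
blood pool that makes real LGE hard. Passing the desk-scale tests therefore
demonstrates that the pipeline's machinery is correct and that the
constraints act in the intended direction — not that clinical-grade accuracy
would be reached on patient data.

## Pre-processing

The chain is crop → reshape → adaptive equalisation → denoising, all on the
cropped grid (running the intensity steps on the small crop is cheaper and
uses the same local statistics).

* **Crop**: an in-plane window centred on the LV-cavity centroid (pooled
  over slices, 0-based integer coordinates), zero-padded where it overruns
  the image so the centroid stays centred; slices are zero-appended up to
  the target count (96×96×16 at full scale, 48×48×8 for the desk profile).
  The geometry record makes `restore_geometry()` an exact integer inverse —
  a property tested, not assumed. At test time the centroid comes from a
  first-pass anatomical prediction on a centre crop, falling back to the
  image centre.
* **CLAHE** (via EBImage): defaults `tile = 4`, `limit = 1.5` (EBImage's
  clip-factor convention). Tiles must stay larger than the LV wall: with
  8×8 tiles on a 48-pixel grid each 6-pixel tile contains essentially one
  tissue and local equalisation erases the inter-tissue contrast (measured:
  the scar/myocardium mean separation collapses from 0.35 to 0.07).
* **Non-local means**, slice-wise, patch 5, search window 11, strength
  `h = 1.2 σ̂` with σ̂ the median-absolute-deviation estimate from row
  differences; `h = 0` is the exact identity. Implemented per displacement
  with an integral image, so cost is independent of patch size.

## Desk-scale profile and problem sizes

`fast_dev_config()` fixes the study conditions used by the tests and the
acceptance script: 48×48×8 phantoms at (1.5, 1.5, 8) mm, base-8 depth-2
networks, 250 anatomical steps (batch 2), 300–550 CVAE steps (batch 4),
420 pathological steps per member (patch batch 4), a 5-member ensemble at
grid positions {0.01, 0.15, 0.22, 0.36, 0.50}, quorum 3. Learning rates are
raised relative to the full-scale recipe (2e-3 anatomical, 1e-3
pathological, 2.5e-3 CVAE): the published rates are tuned for long schedules
and large effective batches and underfit badly within a few hundred
desk-scale steps. `train_config()` keeps the full-scale defaults.

Two post-processing constants are resolution-dependent and are scaled by the
pipeline on sub-96 grids: the 3×3 opening (the phantom wall is ~3 px wide at
48×48, so the same physical regularisation is below one pixel — the opening
is disabled) and the 64-voxel component threshold (scaled by the in-plane
area ratio to 16, matching the proportionally smaller desk-phantom lesions).
`postprocess()` itself keeps the full-scale defaults and its exact
63-removed / 64-retained semantics.

## Numerical choices

* ε = 1e-6 smoothing in every ratio loss; absent classes contribute zero
  rather than 0/0. The pinned optima (−1, 0) hold to 1e-4 on 4³ grids.
* Softmax and cross-entropy are computed with max-shift and probability
  clamps; CVAE log-variances are clamped to ±10.
* Majority-vote ties between scar and MVO go to scar; sub-quorum voxels keep
  the anatomical label.
* Hausdorff distances use 6-connectivity boundary extraction and
  spacing-scaled Euclidean distances; the symmetric max-of-both-directions
  variant is reported by default (standard challenge practice) with the
  directed form available — callers comparing against single-direction
  definitions should say which they use. Empty masks yield `NA`, never 0.
* Both-empty Dice is defined as 1 (agreement on absence), which matters for
  MVO-free cases.
* `AVDR` is reported in percent of the manual myocardium volume
  (classes {2,3,4}).
* All training is seed-reproducible at the loss-trajectory level; one global
  seed fans out to per-stage seeds by fixed offsets.

## Known limitations

* The backward passes are hand-derived; they are pinned by finite-difference
  tests, but the engine supports only the layer set used here (convolution,
  max-pool, nearest upsampling, instance/batch norm, dense heads).
* Batch-norm running statistics come from small desk-scale batches; at full
  scale longer schedules would be needed before the inference-time
  statistics stabilise.
* MVO detection at desk scale is weak (the cores are a few dozen voxels and
  the ensemble rarely reaches quorum on them); the pipeline reports MVO
  presence accuracy rather than pretending to a Dice it cannot support —
  mirroring the difficulty the clinical literature reports for MVO.
* The ensemble roster defaults to paired (λ_IC, λ_CC) values along the grid
  diagonal; the full Cartesian product is available
  (`lambda_grid(cartesian = TRUE)`) but multiplies training cost by eight.
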