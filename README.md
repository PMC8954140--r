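# lgeseg

Multi-class segmentation of left-ventricle myocardial pathology from
short-axis late-gadolinium-enhancement (LGE) cardiac MRI, for image-analysis
researchers who want a fully self-contained, CPU-scale implementation of a
constraint-based two-stage pipeline:

1. an **anatomical U-Net** segments background, LV cavity and myocardium
   (loss `L = L_CE + L_Dice`, with the multi-class Dice term
   `L_Dice = -(2/|K|) Σ_k [Σ_i u_ik v_ik / (Σ_i u_ik + Σ_i v_ik + ε)]`);
2. a **pathological 3D U-Net** relabels the pre-segmented myocardium into
   healthy wall, infarct scar and microvascular obstruction (MVO), trained
   with `L_final = L_Seg + λ_IC·L_IC + λ_CC·L_CC`, where `L_Seg` is one
   minus the mean soft IoU, `L_IC = Σ_i ||RP_i − RG_i||²_F` compares frozen
   CVAE shape-model reconstructions of prediction and ground truth, and
   `L_CC` is a patient-level (infarcted vs normal) cross-entropy on a head
   attached to the U-Net bottleneck;
3. one network per constraint weight along the grid
   `λ ∈ {0.01, 0.08, …, 0.50}` is fused by per-voxel **majority voting**
   (quorum 3 for pathological labels, plurality with ties to scar), followed
   by slice-wise 3×3 opening and 3D connected-component filtering
   (components < 64 voxels removed).

The package ships the full evaluation suite used in challenge practice
(Dice, Hausdorff distance in mm, absolute volume difference AVD and its rate
AVDR = AVD/V_MYO, MVO presence accuracy per case and slice, patient
classification metrics, Bland–Altman summaries) and a **synthetic short-axis
phantom generator** — nested cavity/myocardium rings with scar wedges and
MVO cores, stratified 33/27/40 per 100 cases — so every stage trains and
evaluates without any external data. The conv-net engine is a compact
CPU implementation (Rcpp/RcppArmadillo, im2col + BLAS) with hand-derived,
finite-difference-verified backward passes.

## Worked example

The desk-scale profile (48×48×8 phantoms, base-8 networks, a 5-member
ensemble) runs the whole simulate → train → predict → evaluate chain in
roughly a quarter of an hour on one CPU core:

```r
library(lgeseg)

res <- run_pipeline(fast_dev_config(), seed = 1)
round(res$report$summary, 3)
#>  dsc_myocardium   hd_myocardium  avd_myocardium avdr_myocardium          dsc_mi
#>           0.951           2.074        1522.800           6.241           0.847
#>           hd_mi          avd_mi         avdr_mi         dsc_mvo          hd_mvo
#>           6.396         702.000           2.694           0.800             NaN
#>         avd_mvo        avdr_mvo
#>         279.000           1.100
round(res$report$classification, 1)
#> sensitivity specificity   precision    accuracy
#>         100         100         100         100
res$topology_violations
#>  [1] 0 0 0 0 0 0 0 0 0 0
```

Reading: on the 10 held-out phantoms the fused, post-processed maps overlap
the ground-truth myocardium at Dice 0.95 (mean boundary error 2.1 mm), the
infarct at Dice 0.82 averaged over all cases, every case is classified
correctly as infarcted/normal, and no pathology voxel ends up outside the
myocardial region (`check_topology` class-(a) count 0 on all cases).
`hd_mvo` is `NaN` because Hausdorff is undefined (reported missing, not 0)
when a mask is empty — the ensemble rarely reaches quorum on the tiny MVO
cores, so MVO is scored by presence accuracy instead
(`res$report$mvo_accuracy`).

Individual stages are available as ordinary functions: `generate_cohort()`,
`preprocess_case()`, `train_anatomical()` (five-fold CV with a per-fold
metrics table), `pretrain_cvae()`, `train_pathological()`,
`predict_case()`, `majority_vote()`, `postprocess()`, `evaluate_cohort()`.

A command-line wrapper with `simulate | train | predict | evaluate`
subcommands is installed at `inst/cli/lgeseg`:

```sh
Rscript inst/cli/lgeseg simulate --n 40 --strat 13,14,13 --out phantoms/ --seed 7
Rscript inst/cli/lgeseg train --out ckpt/ --seed 7
Rscript inst/cli/lgeseg predict --input phantoms/case001.nii.gz \
    --checkpoint-dir ckpt/ --out seg.nii.gz
Rscript inst/cli/lgeseg evaluate --pred-dir preds/ --gt-dir phantoms/ --out report.csv
```

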