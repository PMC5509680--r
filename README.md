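# mparseg

Fully automatic localization and segmentation of tumours on
multiparametric MR volumes, for image-analysis researchers who need a
transparent, dependency-light reference implementation of the classic
patch-based approach — and a synthetic phantom world to test it in.

## The problem and the method

On high-b diffusion-weighted imaging (DWI) cellular tumour tissue is
bright, but so are lymph nodes, glands, fluid and fat-suppression
artefacts; single-sequence thresholding therefore needs expert
correction. `mparseg` instead classifies every voxel from its
multiparametric context: the in-plane \(M \times M\) patch around voxel
\(v\) in three co-registered sequences (T2w, DWI b≈0, high-b DWI) is fed
to a nine-layer convolutional network

> conv(5×5) → conv(5×5) → pool → conv(3×3) → pool → conv(3×3) → pool → fc → softmax,

with feature counts 24/48/96/192 (360 filters in total), yielding a
probability map \(p(v)\). The segmentation is the largest 3D connected
component of \(\{v : p(v) \ge 0.5\}\).

Training patches are class-balanced and region-stratified: per subject,
\(N\) tumour centres plus \(N/4\), \(N/2\), \(N/4\) background centres
from (B1) the 10 mm shell around the tumour, (B2) other DWI-hyperintense
voxels — after per-sequence standardization to mean 0/SD 1 this stratum
is simply "standardized high-b intensity > 2.00" — and (B3) everything
else. The network is trained with Adadelta on cross-entropy + small L2,
stopping when the held-out patch cost has not improved by more than
10⁻³ for five consecutive epochs.

Evaluation: per-subject Dice similarity coefficient
\(\mathrm{DSC} = 2|A \cap B| / (|A| + |B|)\) of the final masks, tie-aware
voxelwise ROC AUC of the probability maps, and — across repeated
sampling/training runs — agreement of per-subject DSC via ICC(2,1)
(two-way random effects, absolute agreement) with an F-based 95% CI.

Everything runs on synthetic multiparametric phantoms (spherical tumour
hyperintense on high-b DWI, configurable distractor spheres, optional
artefact bands, ghosting and channel misalignment), written as NIfTI with
plain-text cohort manifests, so the whole pipeline is testable without
patient data.

## Worked example

Desk-scale end-to-end experiment — 30 phantom subjects of 64×64×16 voxels
at 2×2×5 mm (20 discovery / 10 held out), 500 patches per class per
subject, patch edge 11, conv widths 4/8/16/32, 15-epoch cap (about seven
minutes on one CPU):

```r
library(mparseg)
res <- run_experiment(desk_scale_config(seed = 1))
res$metrics
#> <metrics_report> 10 subjects: DSC 0.880 (SD 0.026), AUC 1.000 (SD 0.000)
```

The held-out probability maps rank tumour voxels essentially perfectly
(AUC ≈ 1.0); the final masks overlap the truth at DSC ≈ 0.88, the gap
being a thin over-called halo at the tumour boundary — the expected
signature of training on artificially class-balanced patches.

The classic failure mode is reproduced on demand: a distractor sphere
with the tumour's own intensity profile but a larger radius wins the
largest-component selection, so DSC collapses to 0 while the map's AUC
stays high:

```r
fm <- failure_mode_case(res$model, res$config)
c(auc = round(fm$auc, 3), dsc = fm$dsc)
#>   auc   dsc
#> 0.994 0.000
```

A command-line driver covers the same ground
(`inst/exec/mparseg phantom|preprocess|sample|train|predict|evaluate|stability|run-all`).

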