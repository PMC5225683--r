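# liverseg

Fully automatic liver-envelope segmentation for contrast-enhanced abdominal
CT, in R. The package is aimed at medical-image-analysis researchers and
tool builders who need a self-contained, deterministic liver segmentation
pipeline plus the standard overlap metrics to score it — with no manual
initialization, no shape model, and no training data.

## Method

Each axial slice is represented as a weighted pixel graph. An edge between
neighboring pixels *i*, *j* carries

```
W_ij = exp(-beta (g_i - g_j)^2) * exp(-((x_i-x_j)^2 + (y_i-y_j)^2)/lambda_s) + omega
```

and, given automatically placed liver/background/lesion seeds, the
probability that a random walker starting at a pixel first reaches a seed
of label *L* is the harmonic extension of the seed indicator — the solution
of the combinatorial Dirichlet problem `L_U x_U = -B^T m_L` on the
seeded/unseeded block decomposition of the graph Laplacian `L = D - W`.
Only `L - 1` sparse SPD systems are solved per slice (Cholesky, factorized
once); the last label follows from the unit-sum complement, and each pixel
takes its maximum-probability label.

Around this core the pipeline runs: Canny-based table/background removal,
top-/bottom-hat edge enhancement, exact 3×3 median denoising; liver-dome
detection from two consecutive ≥ 10 % right-lung-area decreases;
ribcage-interior masking by a closed cubic B-spline through rib centroids
(De Boor's recursion); automatic seeding (≤ 1200 seeds/slice, half liver,
half background, deterministic sub-grids) with slice-to-slice propagation
and lesion-outlier seeding; and the five standard measures — VOE,
precision, accuracy, DSC, signed RVD — for evaluation. A deterministic
synthetic CT phantom with ground-truth masks makes the whole pipeline
testable without clinical data.

## Worked example

```r
library(liverseg)

ph  <- generate_phantom(phantom_preset("multi-lesion", shape = c(40, 256, 256), seed = 7))
seg <- segment_series(ph$volume)
seg
#> <liver_segmentation> dome 12, middle 24, last 31; liver voxels 22177

compute_report(seg$liver_mask, ph$masks$liver)
#> VOE 4.08%  DSC 0.9792  precision 0.9926  accuracy 0.9996  RVD -2.66%
#> TP 22012  FP 165  FN 771  TN 2598492
```

The phantom's liver spans slices 12–32 with its widest cross-section at
slice 20; the pipeline localizes the dome at slice 12 from the lung-area
drops, calibrates liver intensity on slices 13–14, and recovers the
envelope with a Dice coefficient of 0.98. (The "middle" slice reported
here is the in-band count argmax, which the preset's lesions shift a few
slices caudally — they subtract from the liver-band counts.) The three
simulated lesions, including one crossing the liver boundary, are seeded
as their own label and merged back into the envelope. VOE is the
volumetric overlap error (0 = perfect); the negative RVD indicates slight
under-segmentation, mostly the few-voxel caudal tip.

The same pipeline runs from the shell via the thin CLI:

```sh
Rscript inst/cli/liverseg.R phantom  --preset healthy --output vol.nii.gz --masks-prefix gt
Rscript inst/cli/liverseg.R segment  --input vol.nii.gz --output mask.nii.gz
Rscript inst/cli/liverseg.R evaluate --segmented mask.nii.gz --truth gt_liver.nii.gz
```

Input volumes are NIfTI (`.nii`/`.nii.gz`); DICOM series should be
converted (e.g. `dcm2niix`) first.

## Package layout

- `R/volume_io.R` — NIfTI I/O, HU windowing, CT volume container
- `R/preprocess.R` — Canny body detection, top-/bottom-hat, median
- `R/anatomy.R` — lungs, liver dome, middle/last-slice rules
- `R/ribcage.R` — rib centroids, De Boor closed B-spline, interior masking
- `R/random_walker.R` — pixel graph, Laplacian, Dirichlet solve, labelling
- `R/seeding.R` — initial/propagated/lesion seeds
- `R/metrics.R` — VOE, precision, accuracy, DSC, RVD
- `R/phantom.R` — synthetic CT phantom generator with ground truth
- `R/pipeline.R` — orchestration, configuration, diagnostics
- `vignettes/liver-random-walker.Rmd` — models, parameters, limitations
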