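---
title: "Automated infarct segmentation on LGE-CMR: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated infarct segmentation on LGE-CMR: models, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After an ST-elevation myocardial infarction, the size of the infarct scar and
the presence of microvascular obstruction (MVO) on late-gadolinium-enhancement
(LGE) cardiac MR are strong predictors of adverse outcome. Quantifying them
requires segmenting every short-axis slice — slow, and poorly reproducible
across human readers. `infarctseg` implements a fully automated two-stage
pipeline for this task, the semi-automated thresholding procedure that human
readers use, and the statistical toolbox needed to compare the two, all
exercisable end-to-end on synthetic phantoms.

## The pipeline

Stage 1 (**localization**) segments the left ventricle (LV) on the full grid,
takes the center of mass of the binarized middle-slice mask, and extracts a
centered, reduced-size stack (default 96 x 96 voxels at the native in-plane
spacing). Stage 2 (**error-correcting 2D–3D cascade**) performs multiclass
segmentation — background, blood pool, myocardium, scar, MVO — on the crop: a
2D model labels each slice independently (slices are abundant training
samples), and a 3D corrector receives the image together with the one-hot
candidate mask and re-labels every voxel using inter-slice context. The
corrector is trained on deliberately *perturbed* masks, so it learns to repair
the error modes a per-slice segmenter actually makes.

### Model realization

Each of the three networks is realized as a multilayer-perceptron voxel
classifier (`nnet`) over multiscale neighborhood features:

* localizer — z-scored intensity plus per-slice Gaussian-pyramid intensities
  (sigma 2 and 5 voxels);
* 2D segmenter — intensity, pyramid (sigma 1, 3, 6) and normalized radial
  position within the LV-centered crop;
* 3D corrector — image features plus, per class, the one-hot candidate mask,
  its in-plane smoothing (sigma 2) and its mean over the slice neighborhood
  (z-1, z, z+1).

At the fidelity of short-axis LGE data — a handful of well-separated tissue
intensity distributions arranged in a ring geometry — these features carry the
same information a small convolutional encoder–decoder would extract, while
training deterministically in seconds on a single CPU; every capacity
(hidden units, iterations, sampling budget) lives in the stage configs
(`localizer_config()`, `seg2d_config()`, `corrector_config()`). The design
keeps all stage contracts: per-voxel class probabilities summing to one,
shape preservation, and bit-reproducible training under a fixed seed. What it
gives up is learned spatial filters, which matters on real data with textured
backgrounds; see *Limitations*.

### Perturbation operators

"Perturbed masks" is concretized as five operators applied per slice to the
scar and MVO components: morphological dilation and erosion (disc radius 1–2),
deletion of a connected component, insertion of a spurious scar blob inside
the myocardium, and a scar/MVO class swap inside the scar core. Together they
span over-segmentation, under-segmentation, false positives and the
scar-vs-MVO confusion that are the plausible per-slice error modes. During
corrector training the candidate mask is perturbed ground truth with
probability 0.7, and the frozen 2D model's actual prediction otherwise, so
the corrector sees both injected and real errors.

## The threshold reference method

The manual reference procedure is: draw epi- and endocardial contours, place
a small ROI in the remote (healthy) myocardium, and mark as scar every
myocardial voxel whose intensity is at least `mean + k * SD` of the remote
ROI, with `k = 5`. `remote_stats()` / `threshold_scar()` implement this with
two documented choices: the boundary rule is `>=` (configurable to `>`), and
the remote SD is the population SD (configurable to sample SD) — the
procedure's sources do not fix either, and both choices only matter within a
hair of the threshold. Whether the hypointense MVO core counts toward infarct
volume is a reporting policy (`include_mvo_core()`, union by default).

## The phantom generator

`phantom_params()` / `generate_dataset()` emulate the structure of a
short-axis LGE cohort after reperfused STEMI:

* grid 12 x 128 x 128 at (8, 1.5, 1.5) mm — typical LGE anisotropy: few thick
  slices, fine in-plane;
* the LV as a per-slice annulus (blood pool inside a myocardial ring) whose
  radii taper to 55% toward the apex, with the axis position drawn uniformly
  over a +/-18-voxel box so localization is non-trivially exercised;
* scar as a subendocardial angular wedge (40–120 degrees, transmurality
  0.4–1.0) on a contiguous band of slices — every case has scar
  (`scar_probability = 1`, an all-STEMI cohort);
* an MVO core in 15% of scarred cases, occupying the inner, angularly central
  part of the wedge on the central scar slices;
* class-mean intensities (background 50, blood 320, myocardium 200, scar 450,
  MVO 170, arbitrary units) with additive Gaussian noise (SD 25). Scar is
  markedly hyperintense; MVO sits below remote myocardium, reflecting that
  MVO intensity is close to healthy muscle and is the hard class.

What the phantom does **not** model: Rician noise statistics, partial-volume
blur at tissue boundaries, papillary muscles, LV outflow-tract blood, motion,
surface-coil intensity gradients, or anatomy-dependent scar shapes. Passing
the simulation bars therefore demonstrates that the pipeline's machinery is
correct and self-consistent — not that it reaches any particular accuracy on
clinical images.

## Numerical choices

* Indexing is 1-based `(slice, row, col)`; the middle slice of an `n`-slice
  stack is `floor(n/2) + 1`, the same physical slice as `floor(n/2)` in
  0-based conventions.
* Localizer output is binarized at 0.5; degenerate predictions fall back from
  middle-slice center of mass to the 3D center of mass to the grid center
  (with a warning).
* Argmax over class probabilities breaks ties toward the lower class code.
* Crops overhanging the grid are zero-padded (images) or background-labelled
  (labels); `uncrop()` is the exact inverse on in-grid voxels.
* In-plane resampling aligns grids at their physical centers and sizes the
  output as `round(extent / target)`, preserving extent within one voxel;
  labels use nearest-neighbour only.
* The empty-vs-empty Dice is defined as 1 (correctly absent structure).
* Lin's concordance uses population moments; its CI uses the asymptotic
  variance of the Fisher z-transformed coefficient.
* Bland–Altman differences are `manual - automatic`; limits of agreement use
  the sample SD.
* Confidence intervals for proportions are exact binomial (Clopper–Pearson
  Beta quantiles): this is the method that reproduces reference bounds such
  as a 97.6% lower limit for 152/152 successes.
* Rating-table CIs use a parametric multinomial bootstrap (B = 10,000,
  percentile interval, seeded).
* The Wilcoxon signed-rank test uses the exact distribution up to n = 25
  non-zero, non-tied differences and drops zero differences.

## Problem sizes and reproducibility

The package's own simulation study — used by the test suite and by
`scripts/acceptance.R` — trains on 30 phantoms and evaluates on 10 held-out
phantoms at full 12 x 128 x 128 resolution; this size comfortably separates a
working pipeline from a broken one (the acceptance bars are a localization
error within 5 voxels in at least 9/10 cases, mean held-out scar Dice of at
least 0.70, and a corrector that costs at most 0.02 Dice) while keeping a
complete run under a minute. Every stochastic stage receives a seed derived
from one master seed, and `run_pipeline()` echoes its full configuration into
the report, so any report is reproducible from its config alone.

```{r}
library(infarctseg)
report <- run_pipeline(pipeline_config(seed = 1))
print(report)
report$summary
autoplot(report$bland_altman)
```

## Limitations

* The voxel-feature classifiers have no learned spatial filters; on clinical
  images with heterogeneous backgrounds and coil shading, a convolutional
  architecture slotted behind the same stage interfaces would be the
  appropriate upgrade — the contracts (`predict_localizer()`,
  `predict_seg2d()`, `predict_corrector()`) are architecture-agnostic.
* The phantom's simplifications listed above mean simulation metrics should
  never be quoted as expected clinical performance.
* MVO segmentation is intrinsically hard (small, rare, near-isointense with
  healthy myocardium); the pipeline predicts it but no accuracy bar is set
  for it, mirroring how it is the weak point of automated methods generally.
* Orientation metadata is passed through opaquely; volumes are assumed to be
  short-axis stacks already.
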