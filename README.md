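# infarctseg

Fully automated myocardial infarct segmentation for short-axis
late-gadolinium-enhancement (LGE) cardiac MR, with the semi-automated 5-SD
threshold reference method and the complete statistical toolbox for comparing
automated and human segmentations.

**Who it is for.** Researchers quantifying infarct scar and microvascular
obstruction (MVO) after reperfused myocardial infarction: infarct size drives
risk stratification, but manual per-slice segmentation is slow and poorly
reproducible. The package provides (a) an automatic pipeline that needs no
user interaction, (b) the thresholding procedure human readers use, so both
routes are available on the same data, and (c) evaluation statistics down to
reader-study level. A built-in phantom generator makes the whole pipeline
runnable and testable without any clinical images.

## The method

**Pipeline.** A localizer segments the left ventricle (LV) on the full stack;
the center of mass of the binarized middle-slice mask defines a centered,
reduced-size crop (default 96 x 96). On the crop, an error-correcting 2D–3D
cascade performs multiclass segmentation (background, blood pool, myocardium,
scar, MVO): a 2D model labels each slice independently, and a 3D corrector —
trained on deliberately perturbed masks — re-labels every voxel using the
candidate mask plus inter-slice context, repairing per-slice error modes
(over/under-segmentation, dropped or spurious components, scar/MVO swaps).

**Threshold reference.** Given myocardial contours and a remote-myocardium
ROI, scar is every myocardial voxel with intensity ≥ mean + k·SD of the
remote ROI (k = 5 by default).

**Evaluation.** For predicted and reference voxel sets P and G:

    DCS  = 2|P ∩ G| / (|P| + |G|)        (1 when both sets are empty)
    AVD  = ||P| − |G|| × voxelvolume      (mL)
    AVDR = AVD / V_MYO                    (% of LV myocardial volume)

plus infarct size as % of LV mass, Lin's concordance ρc, Bland–Altman limits
of agreement, paired Wilcoxon tests, exact binomial (Clopper–Pearson) CIs,
parametric-bootstrap rating tables, one-way χ² preference tests and
(linearly weighted) Cohen's κ.

## Worked example

Generate a phantom cohort, run the full study, and inspect the results:

```r
library(infarctseg)

report <- run_pipeline(pipeline_config(seed = 1))
print(report)
#> <pipeline_report>
#>   30 train / 10 held-out phantoms (seed 1)
#>   held-out scar Dice: mean 0.997 (min 0.991)
#>   localization error: median 0.4 voxels
#>   infarct size (% LV mass): rho_c = 1.000, bias -0.00%
```

The held-out scar is recovered with a mean Dice of 0.997, every crop center
lands well within 5 voxels of the true LV axis, and automated infarct sizes
(% of LV mass) agree with the reference almost perfectly on these phantoms.
`report$metrics` holds the per-case Dice/AVD/AVDR table (corrected and
2D-only stages), `report$bland_altman` and `report$concordance` the agreement
analyses (`autoplot(report$bland_altman)` draws the plot).

The threshold reference method on a single phantom:

```r
ca  <- generate_case(phantom_params(), 42)
roi <- remote_roi(ca)                    # remote-septum sector of the ring
remote_stats(ca$image, roi)
#> remote myocardium: mean 202.16, population SD 24.30 (n = 60) -> 5-SD threshold 323.65
```

Reader-study statistics from per-patient detection calls:

```r
t <- contingency_2x2(tp = 15, fp = 4, fn = 8, tn = 125)
sens_spec(t)[, c("measure", "display_pct", "display_lo", "display_hi")]
#>       measure display_pct display_lo display_hi
#> 1 sensitivity          65       42.7       83.6
#> 2 specificity          97       92.3       99.1

cohen_kappa(matrix(c(20, 10, 5, 15), 2, 2))
#> Cohen's kappa = 0.400 (none weighting, n = 50): fair agreement
```

Sensitivity 65% here means 15 of 23 MVO-positive patients were detected; the
bracketed values are exact binomial 95% confidence bounds.

A command-line front end with subcommands (`phantom`, `train-localizer`,
`train-2d`, `train-3d`, `predict`, `threshold-ref`, `evaluate`,
`diagnostics`, `ratings`, `run-all`) is installed at
`system.file("cli", "infarctseg.R", package = "infarctseg")`.

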