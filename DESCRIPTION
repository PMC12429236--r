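Package: infarctseg
Title: Automated Myocardial Infarct Segmentation and Evaluation on LGE-CMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fully automated myocardial infarct segmentation for short-axis
    late-gadolinium-enhancement (LGE) cardiac MR stacks: left-ventricle
    localization with a centered crop, an error-correcting 2D-3D cascaded
    multiclass segmenter (background, blood pool, myocardium, scar,
    microvascular obstruction), and the semi-automated n-SD threshold
    reference method. Ships a synthetic short-axis LGE phantom generator so
    the whole pipeline is exercisable without clinical data, plus the full
    evaluation toolbox: Dice and absolute-volume-difference metrics, Lin's
    concordance, Bland-Altman analysis, paired Wilcoxon tests, exact binomial
    (Clopper-Pearson) confidence intervals, parametric-bootstrap rating
    tables, one-way chi-square preference tests and (weighted) Cohen's kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    ggplot2,
    nnet,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
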