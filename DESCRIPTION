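Package: preclinq
Title: Quantification and Group Analysis for Preclinical Multimodal
    Neuroimaging Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying preclinical (mouse) neuroimaging readouts
    and testing genotype effects across brain regions. Implements
    pseudo-continuous arterial spin labeling (pCASL) cerebral-blood-flow
    quantification with inversion-efficiency estimation and whole-brain ratio
    normalization; Cramer-Rao lower bound (CRLB) quality control, pooled
    z-scores and Bonferroni-corrected group tests for 1H-MRS metabolite
    concentrations; robust monotone standard-curve calibration of film
    autoradiography optical densities to specific radioligand binding; and
    genotype-by-region split-plot ANOVA with Bonferroni post-hoc tests,
    ANCOVA covariate adjustment, and effect-size conversions from test
    statistics (Cohen's d, partial eta squared). A layered synthetic-cohort
    generator with known ground truth makes every stage testable without
    access to raw scanner or film data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    minpack.lm,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
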