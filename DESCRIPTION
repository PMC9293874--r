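Package: rtnf
Title: Simulation and Analysis of Real-Time fMRI Neurofeedback Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale simulation and analysis of posterior
    cingulate cortex (PCC) targeted real-time fMRI neurofeedback studies
    with a block-design mindfulness paradigm. Provides generators for
    synthetic BOLD volume series with known ground truth (task effects,
    Legendre drift, cardiac/respiratory physiology, motion coupling), the
    per-volume real-time processing chain (masked Gaussian smoothing,
    percent-signal scaling over an initial baseline window, streaming
    nuisance regression over motion, RETROICOR, tissue and polynomial
    regressors), the neurofeedback bar rule (preceding-rest baselines,
    onset gating, moving-average smoothing, target levels), offline
    analysis (despiking, RETROICOR/RVT correction, run-level GLM with
    percent-signal-change contrasts, spherical ROI extraction, group
    t-maps, PPI connectivity with framewise-displacement censoring), and
    the group statistical battery (one-sample t, linear mixed-effects
    models with Tukey follow-ups, Cohen's f, ICC(3,k), Bonferroni-adjusted
    correlations, repeated-measures ANOVA power).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    multcomp,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
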