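Package: connbs
Title: Connectome-Wide Network-Based Statistic Analysis of Treatment Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for connectome-wide analysis of intrinsic functional
    connectivity in clinical cohorts. Builds Fisher-z functional connectomes
    from denoised region-level BOLD time series (volume censoring by framewise
    displacement and DVARS, nuisance regression with Volterra-expanded motion
    parameters and spike regressors, zero-phase band-pass filtering), applies
    the Network Based Statistic (edge-wise two-sample tests, component-forming
    threshold, permutation null of the maximal connected-component extent) to
    identify subnetworks separating treatment remitters from non-remitters,
    summarises the identified signature per subject overall and by
    intrinsic-network pair, and runs the staged group and longitudinal
    statistics (outcome-by-drug and case-control ANOVA, mixed time-by-group
    ANOVA with post-hoc contrasts, Benjamini-Hochberg FDR, and cross-validated
    classifier comparison of the signature's added predictive value). Includes
    a synthetic-cohort generator with planted differential subnetworks and
    recorded ground truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    signal,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'connbs-package.R'
    'connectome.R'
    'cv.R'
    'denoise.R'
    'group-stats.R'
    'nbs.R'
    'parcellation.R'
    'pipeline.R'
    'signature.R'
    'synthetic-cohort.R'
    'synthetic-timeseries.R'
    'utils.R'
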