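Package: luminrate
Title: Rate-Based Drug-Response Analysis of Continuous Luminescence Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying in vitro drug response from real-time
    (continuous) luminescence viability assays. Luminescence rates are
    extracted from plate-reader time courses by enumerating trailing slices of
    timepoints anchored at the end of the assay (defined by peak control
    luminescence) and keeping the slice whose linear regression maximizes R
    squared. Drugged-well rates are normalized to the undrugged basal rate and
    fitted to a four-parameter log-logistic dose-response model, from which
    drug effects are classified as cytotoxic, cytostatic, anti-proliferative
    or absent. Paired comparison of EC50 estimates between measurement
    channels (luminescence versus direct cell counting) uses an exact
    enumeration Wilcoxon signed-rank test. A mechanistic plate simulator with
    exponential growth, reagent depletion and multiplicative noise provides
    ground truth for validation. Plate data are stored in a
    SummarizedExperiment-derived container.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    yaml,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Pharmacogenomics, TimeCourse,
    Regression
RoxygenNote: 7.3.3
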