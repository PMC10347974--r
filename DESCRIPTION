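Package: synergyscreen
Title: Multi-Model Synergy Scoring and Consolidation for Drug Combination Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput drug combination viability
    screens on patient-derived cultures: four-parameter Hill monotherapy
    fitting with absolute-IC50 sensitivity filtering, dose-matrix assembly
    with DMSO normalization, reference-model synergy surfaces (Loewe
    additivity, highest single agent, Bliss independence, Chou-Talalay
    combination index) summed into signed synergy/antagonism scores plus
    minimum viability, z-scale consolidation with Gaussian-mixture
    model-based clustering and K-means validation to call consistently
    synergistic combinations, longitudinal synergy classification against a
    randomization null, and a fully synthetic screen generator with known
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'doseresponse.R'
    'grids.R'
    'surfaces.R'
    'consolidate.R'
    'longitudinal.R'
    'cohort.R'
    'synthdata.R'
    'pipeline.R'
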