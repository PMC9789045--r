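Package: enspff
Title: Quantification of Alpha-Synuclein Preformed-Fibril Uptake and Activity
    in Enteric Neuron Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable reimplementation of the quantification stack
    used to study alpha-synuclein preformed-fibril (PFF) uptake in cultured
    enteric neurons: morphology segmentation of immunofluorescence
    micrographs into neuron/soma/neurite compartments, per-compartment
    intensity metrics (mean intensity, elevated-area fraction, maximum
    intensity, nuclei counts), extracellular spike and burst detection from
    microelectrode-array voltage traces, and the study's hierarchical
    statistical layer (variance-stabilising transforms, multilevel models
    selected by likelihood ratio, Tukey-adjusted marginal-mean contrasts,
    Kruskal-Wallis/Wilcoxon with Benjamini-Hochberg adjustment, and a
    zero-inflated negative-binomial multilevel count model). Ground-truthed
    synthetic image scenes, voltage traces and hierarchical outcome tables
    make the whole pipeline testable without the original raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    lme4,
    glmmTMB,
    emmeans,
    tiff,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    rlang,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
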