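Package: itimarker
Title: Inter-Train-Interval EEG Biomarker Analysis for rTMS Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for EEG biomarkers of repetitive transcranial
    magnetic stimulation (rTMS) treatment trials. Implements a 64-channel 10-10
    scalp montage with homologous left/right pairing, segmentation of
    inter-train-interval (ITI) EEG into post-train epochs, average-reference and
    spherical-spline current-source-density (CSD) re-referencing, Welch spectral
    estimation and band power, the low-gamma/alpha power-ratio biomarker,
    whole-scalp correlation maps with cluster-based Monte-Carlo permutation
    correction, inter-hemispheric balance models based on partial correlations
    with false-discovery-rate control, TMS-evoked potential (TEP) component
    analysis, and the clinical outcome layer (mixed ANOVA, effect sizes,
    responder rates, Fisher exact tests). Includes a synthetic rTMS-EEG cohort
    generator with planted, ground-truthed couplings between the biomarker and
    clinical improvement, used to validate every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
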