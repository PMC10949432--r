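Package: imodulome
Title: iModulon-Based Transcriptional Regulatory Network Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs bacterial transcriptional regulatory networks from
    RNA-seq expression compendia using independent component analysis (ICA).
    Provides compendium quality control (replicate-correlation filtering and
    reference-condition centering), robust ICA over multiple restarts with
    data-driven dimensionality selection, extraction of iModulons
    (independently modulated gene sets) with explained-variance accounting,
    regulon enrichment and recall metrics against a draft regulatory network,
    differential iModulon activity testing, intergenic-distance operon
    clustering, position-specific scoring matrix (PSSM) motif scanning of
    promoter regions, and an imbalance-aware elastic-net classifier of
    regulon membership with operon-grouped cross-validation. A synthetic
    compendium and genome generator with known ground truth supports
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    jsonlite,
    withr,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
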