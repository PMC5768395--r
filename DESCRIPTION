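Package: methylscreen
Title: Multi-Stage Screening and Panel Evaluation of DNA Methylation
    Biomarkers at CTCF-Binding Sites
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements a multi-stage screening workflow for tissue DNA
    methylation biomarkers measured at CTCF-binding sites: candidate
    discovery from cell-line occupancy/methylation association,
    semiquantitative melting-curve (MS-HRM style) triage against a
    0/1/10/100% dilution standard curve, CpG-unit and sample reliability
    filtering for mass-spectrometry (EpiTYPER style) data,
    representative-CpG-unit selection by ROC AUC, bootstrap estimation of
    sensitivity at fixed specificity with DeLong significance tests,
    average-linkage two-way hierarchical clustering of log-methylation,
    and stage-stratified evaluation of m-of-k diagnostic marker panels.
    Ships a calibrated synthetic-data generator emulating a colorectal
    normal/tumor study so the whole pipeline is testable without access
    to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, vegan, yaml
Suggests: testthat (>= 3.0.0), pROC, pheatmap, jsonlite, withr, optparse
Config/testthat/edition: 3
biocViews: DNAMethylation, Epigenetics, BiomarkerDiscovery, Classification
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
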