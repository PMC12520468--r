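Package: dnbtip
Title: Dynamic Network Biomarker Detection of Critical Transitions in
    Time-Course Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects pre-transition "tipping point" states in replicated
    time-course expression data using the dynamic network biomarker (DNB)
    framework: a candidate gene module is scored at every timepoint by its
    within-module standard deviation (SD_in), within-module absolute Pearson
    correlation (PCC_in) and module-to-background correlation (PCC_out),
    combined into a criticality index whose peak locates the tipping point.
    Includes a one-factor simulator with a planted critical transition and
    planted protein-protein interaction neighborhood for ground-truth
    benchmarking, variance-moderated differential expression over timepoint
    contrasts, fuzzy c-means clustering of temporal profiles, permutation
    significance for module scores, and correlation-network construction
    around the detected module (neighbor intersection, gene-set filtering,
    pathway activity scoring, and metastasis-neighbor ranking).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    e1071,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
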