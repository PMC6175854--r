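Package: pronet
Title: Bayesian Integrative Estimation of Cancer-Specific and
    Patient-Specific Protein Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates cancer-specific protein signaling networks from
    multi-platform molecular data (protein, mRNA, microRNA, DNA
    methylation) by node-wise Bayesian variable selection with Zellner
    g-priors, using prior inclusion probabilities calibrated from
    PC-algorithm causal structure learning under subsampling stability
    and protein-protein interaction confidence scores.  Deconvolves
    patient-specific activation statuses of network proteins from
    posterior predictive distributions, summarises them into
    out-degree-weighted pathway activity scores, stratifies patients by
    Ward hierarchical clustering with gap-statistic model selection, and
    provides cross-lineage network summaries (connectivity, diversity,
    edge consistency, predictive concordance) together with a
    multi-platform cohort simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
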