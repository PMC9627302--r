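Package: dcoexnet
Title: Differential Co-Expression Network Modules and Biomarker Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for two-condition transcriptome analysis:
    per-study differential expression with empirical-Bayes moderated
    t-statistics, condition-specific Pearson co-expression networks over the
    common differentially expressed genes, molecular-complex (MCODE-style)
    module detection with loop-excluded scoring, density-based module
    preservation between disease and control states, ROC/AUC biomarker
    screening of module genes, hypergeometric gene-set enrichment, and
    miRNA-target regulatory network construction. Includes a synthetic-data
    generator that plants disease-specific co-expression modules via a
    latent-factor model, so the full pipeline is testable end-to-end with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    limma,
    fgsea,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
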