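Package: methrisk
Title: Epigenome-Wide Blood DNA Methylation and Prospective Cancer Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for prospective epigenome-wide association
    analysis of blood DNA methylation and disease risk in matched
    case-control studies. Covers probe and sample quality-control ledgers,
    k-nearest-neighbour imputation, empirical-Bayes batch adjustment,
    peak-based Infinium type II rescaling, white-blood-cell discriminating
    probe filtering and reference-based cell proportion estimation,
    per-sample genome-wide methylation exposures (quartile and per-SD
    pseudo-continuous), conditional logistic risk models with spline risk
    distributions and ROC summaries, a two-stage probe-wise scan (beta
    regression for technical adjustment followed by a Poisson model with a
    person-years offset), coverage-weighted summaries of pooled
    whole-genome bisulphite sequencing, and cross-study random-effects
    meta-analysis. Includes generators for synthetic data with the
    statistical structure the analysis assumes, so the full pipeline is
    testable without access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    S4Vectors,
    splines,
    sandwich,
    pROC,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    metafor,
    sva,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
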