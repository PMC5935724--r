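Package: medssn
Title: Group-Median Single-Sample Networks for Transcript-Lipid Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-correlation network analysis for small factorial
    designs in which gene-expression fold changes and lipid quantities are
    measured on the same animals. Implements the add-one-sample delta
    Spearman correlation (dSCC) statistic with group medians, z-score edge
    significance and lipid-edge selection, together with the supporting
    computations such studies rely on: delta-delta-Ct relative
    quantification, reference-group normalization, Shapiro-Wilk normality
    screening, Bland-Altman method agreement, pooled-variance group tests,
    hierarchical clustering of expression panels, and a synthetic-study
    generator with planted mean shifts and correlation edges for
    end-to-end validation. Networks are exported as edge tables, SIF and
    GraphML for viewers such as Cytoscape.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
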