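Package: ImmuMiR
Title: Inference of miRNA Regulators of Immune Pathways and an
    Immune-Associated miRNA Prognostic Score
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate miRNA regulators of immune-associated
    pathways from matched miRNA and mRNA expression profiles. For every
    miRNA, genes are ranked by a tumour-purity-adjusted partial
    correlation transformed into a signed rank score, and each immune
    gene set is scored by weighted Kolmogorov-Smirnov enrichment with a
    gene-set permutation null; the permutation p-value and enrichment
    sign combine into a miRES score in [-1, 1] with a dual
    miRES/false-discovery-rate significance filter. Also provides
    single-sample enrichment (ssGSEA) scoring, a packaged three-miRNA
    prognostic risk signature with a maximally selected log-rank
    cutpoint search, a risk-associated drug screen on IC50 tables, a
    synthetic cohort generator with recorded ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
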