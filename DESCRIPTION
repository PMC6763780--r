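Package: neomir
Title: Longitudinal miRNA Response Analysis for Neoadjuvant Therapy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal microRNA expression in
    neoadjuvant treatment cohorts with matched mRNA and protein layers.
    Implements per-sample median centering and presence filtering,
    hierarchical clustering with Pearson correlation distance and recursive
    gap-statistic thresholding (PART) with cluster-clinical association and
    cross-time-point cluster persistence, stratified two-sample Wilcoxon
    differential expression with Benjamini-Hochberg control and fold changes,
    miRNA-mRNA and miRNA-proliferation correlation screens with Bonferroni
    and effect-size filters, a bivariate protein ~ polynomial(mRNA) + miRNA
    regression landscape with hub ranking, target-prediction score filtering
    with correlation/regulation cross-referencing, hypergeometric gene-set
    over-representation, and a seeded synthetic cohort generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
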