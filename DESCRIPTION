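Package: scTMEstats
Title: Downstream Statistics for Single-Cell Tumor-Microenvironment Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable implementations of the bespoke downstream statistics used
    in multi-sample tumor/normal single-cell RNA-seq atlas studies: QC and
    log-normalization of sparse UMI matrices, two-round reclustering with a
    two-way-ANOVA filter that removes sample-driven variable genes, a
    resampling measure of cluster robustness, cluster- and cell-type-
    specificity scores for signature-gene identification, Poisson-GLM testing
    of tumor-versus-normal cluster abundance, correlation dendrograms of
    cluster transcriptomes, a ligand-receptor permutation interaction test
    supporting multi-subunit complexes, gene-set (e.g. exhaustion) scoring,
    and quartile-based grouping of bulk cohorts by signature expression.
    Includes a negative-binomial synthetic-data generator with known ground
    truth (planted markers, batch effects, condition-dependent abundances and
    active ligand-receptor pairs) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    ape,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
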