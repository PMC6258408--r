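Package: burdenRank
Title: Case-Control Gene Ranking for Mendelian Disease Gene Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ranks genes by their rare deleterious-mutation burden in a
    patient cohort relative to a control cohort. Per-individual gene scores
    are computed from normalized variant deleteriousness scores (e.g. CADD)
    under autosomal or X-linked, dominant or recessive inheritance models,
    and case and control score distributions are compared gene-by-gene with
    a zero-inflation-aware two-part statistic: a binomial test on the
    proportion of non-zero scores and a standardized Wilcoxon rank-sum test
    on their magnitudes, combined by Fisher's method into a chi-square
    statistic with four degrees of freedom. Includes a cis-variant
    preprocessing step based on read-coverage concordance and cohort
    co-occurrence, a whole-exome cohort simulator with pathogenic variant
    spike-in driven by an allele-frequency panel, a synthetic panel
    generator, and an evaluation harness computing rank, power and
    candidate-count metrics over simulation replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    IRanges
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
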