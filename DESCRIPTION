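Package: tissueqc
Title: Detect Tissue Heterogeneity in Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality control of bulk and single-cell gene expression profiles
    by single-sample gene-set enrichment testing. Implements a computationally
    efficient tie-corrected Wilcoxon-Mann-Whitney rank-sum test that ranks each
    expression profile once and scores many tissue signatures against the
    precomputed ranks, reporting enrichment scores as |log10 p|. Also provides
    derivation of tissue-enriched gene signatures from tissue-profiled
    expression compendia via the Gini index, seeded simulation frameworks for
    sensitivity analysis (spiked signatures on a Gaussian background, weighted
    mixing of two tissue profiles), and readers and writers for the GMT, TSV
    and GCT 1.2 formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
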