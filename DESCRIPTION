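Package: SigConcord
Title: Overlap and Cross-Modal Concordance Statistics for Drug-Response
    Signatures
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing differential-expression signatures across
    drug treatments, timepoints and molecular modalities. Implements
    signature calling from differential-statistics tables, exact
    hypergeometric and permutation overlap enrichment over an explicit
    background universe, directional-concordance tests against a
    background-derived null, tie-aware Spearman correlation profiles with
    Benjamini-Hochberg correction, construction of gene-protein cross-modal
    background universes, temporal concordance profiling of a fixed
    transcriptomic signature against serial proteomic tables, MAD-based
    quality-control filtering of per-cell metrics, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    SummarizedExperiment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
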