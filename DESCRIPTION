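Package: polyspread
Title: Quantitative Analysis of Polycomb Domain Spreading from Spike-In
    Normalized ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify spreading of H3K27me3 beyond Polycomb
    (SUZ12/RING1B co-bound) binding sites from ChIP-seq with exogenous
    spike-in chromatin (ChIP-Rx). Implements spike-in scaling factors,
    fragment-extended input-subtracted coverage tracks, target-region
    selection from peak calls, the inside/outside boundary density-ratio
    statistic with its comparative tests, reference-point and
    scale-regions profile matrices with shared min-max scaling, and a
    synthetic ChIP-Rx experiment generator with analytic ground truth
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
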