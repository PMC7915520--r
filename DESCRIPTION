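Package: plastiqtl
Title: QTL Mapping of Drought-Plasticity Traits in Biparental RIL Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of phenotypic
    plasticity under water stress in recombinant inbred line (RIL)
    populations. Implements regression-residual plasticity scores
    (phenology-adjusted traits and drought plasticity I/II), variance
    components and broad-sense heritability across irrigation regimes,
    skeleton genetic-map construction and diagnostics (co-segregation
    binning, linkage-group clustering, marker ordering, segregation
    distortion, non-recombinant chromosomes, physical concordance),
    Haley-Knott regression interval mapping with single-QTL,
    two-linked-QTL, joint two-environment and multiple-interval-mapping
    models, permutation-based genome-wide thresholds and bootstrap
    support, rule-based classification of QTLs into phenology-plasticity
    and drought-resistance-strategy categories, and physical anchoring of
    QTL support intervals to gene annotations. A synthetic-data generator
    with a known QTL architecture makes the whole pipeline testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
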