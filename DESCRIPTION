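Package: perinuc
Title: Nuclear Periphery Chromatin Analysis Toolkit
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative tools for studying chromatin positioning at the
    nuclear envelope in fission yeast: spike-in normalized ChIP-seq coverage
    with replicate ribbon profiles, the equal-volume nuclear zoning assay with
    cell-cycle stratification, FRAP one-phase association fitting (half-life,
    mobile fraction), and fluorescent dot detection with colocalization and
    distance-to-edge scoring. Includes synthetic-data generators emulating the
    statistical structure of each input so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    Biostrings,
    minpack.lm,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: ChIPSeq, Normalization, Coverage, Epigenetics, CellBiology
RoxygenNote: 7.3.3
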