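Package: evcargo
Title: Multi-Omic Biomarker Discovery from Extracellular Vesicle Cargo
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering candidate protein and mRNA
    biomarkers carried by extracellular vesicles (EVs) released from cultured
    renal cell lines. Converts TMT isobaric-labeling channel abundances into
    log2 ratios against a pooled reference channel, annotates proteins as
    EV-associated with a two-branch fold-change rule against cell-lysate and
    debris fractions, derives consensus and differential proteome signatures
    across histology groups, performs nCounter-style count normalization
    (positive controls, negative-control background, global median scaling)
    with replicate-consensus presence calling, selects candidate biomarkers by
    detection-based set intersection, and scores enrichment with a weighted
    running-sum GSEA (permutation null, NES, FDR) and hypergeometric
    over-representation analysis. Ships a synthetic-data generator with known
    planted truth so every stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    fgsea,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
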