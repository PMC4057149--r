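Package: ceRNAscan
Title: Prediction and Scoring of lncRNA-mRNA Competing Endogenous RNA Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers microRNA response elements (MREs) on long noncoding and
    protein-coding transcripts by seed-class matching (6mer, 7mer-m8, 7mer-A1,
    8mer and one-mismatch seeds rescued by 3' compensatory pairing) followed by
    a windowed, miRanda-style complementarity alignment; annotates sites with
    conservation and AGO CLIP support projected into transcript coordinates;
    scores candidate lncRNA-mRNA competing endogenous RNA (ceRNA) pairs by the
    shared-MRE ratio and a hypergeometric test on shared miRNAs; and reports
    tissue co-expression of each pair and its shared miRNAs. Includes a fully
    synthetic, seed-reproducible fixture generator so the whole pipeline is
    testable without any external dataset, plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
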