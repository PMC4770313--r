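Package: mirsite
Title: MicroRNA Target Sites Beyond the Seed and Prediction of Protein-Level Repression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects conventional (miRNA 5' seed) and non-conventional (miRNA
    3'-end and central 11-mer) target sites across the 5' UTR, coding region
    and 3' UTR of mRNAs, classifies them into a 54-type taxonomy with
    conservation status, screens site-type counts against protein log2 fold
    changes, and predicts target repression with a compact 9-4-1 feedforward
    neural-network regression over the nine informative site-type counts.
    Includes classification of AGO PAR-CLIP cluster sequences by the kinds of
    miRNA binding motifs they contain, and seeded synthetic-data generators
    with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
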