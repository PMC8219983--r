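Package: slofe
Title: Stem-Loop Free Energy Prediction of Bacterial Operon Stoichiometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers stable intergenic RNA stem-loops from a bacterial
    genome sequence alone, classifies them as transcript stabilizers or
    intrinsic terminators from their downstream poly(U) features, identifies
    operons regulated by selective RNA processing and stabilization (SRPS),
    and predicts per-gene transcript and protein stoichiometry ratios from
    the minimum folding free energy of the controlling stem-loops. Includes
    a normalized read-depth-difference validation statistic, five
    codon-usage baseline predictors (CAI, RCBS, RCA, MELP, gene order), a
    fully synthetic fixture generator with planted ground truth, and an
    end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
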