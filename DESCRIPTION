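Package: exoenz
Title: Comparative Sequence Analysis of Secreted Fungal Enzymes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of exoenzymes secreted by
    entomopathogenic fungi: Blast-score-ratio (BSR) homologue mapping of
    query enzymes against reference proteomes using exact Smith-Waterman
    local alignment with Karlin-Altschul bit scores; neighbor-joining
    phylogenetics on p-distances with bootstrap support; amino-acid
    composition profiling with cold/mesophilic/thermophilic classification
    via pairwise Welch tests and the two-stage Benjamini-Krieger-Yekutieli
    false discovery rate procedure; scanning for lipase and chitinase
    sequence motifs; and seeded synthetic-sequence generators for
    validating every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
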