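Package: promotif
Title: Word-Counting Discovery of Degenerate Promoter Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive word-counting discovery of degenerate DNA regulatory
    motifs in fixed-length promoter sets. Catalogs the promoter-presence of
    every 8-mer oligo over an 11-letter alphabet (A, C, G, T, the two-fold
    wobbles r, y, s, w, m, k, and the wildcard n) or every 12-mer over the
    5-letter alphabet (A, C, G, T, n), scores over-representation in
    co-expressed gene clusters with a hypergeometric upper-tail p-value,
    quantifies position bias toward the transcription start site with a
    discrete-uniform z-score, extracts non-redundant major motifs with a
    position-overlap filter, calibrates false-discovery rates on random
    promoter groups, and supports two-genome comparative analyses via
    conserved p-values over orthologous promoters and cross-genome
    intersection of position-biased motifs. Includes a synthetic promoter
    generator with planted motifs so the whole pipeline is testable without
    external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
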