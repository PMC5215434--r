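Package: ubisitevol
Title: Evolutionary Conservation Analysis of Protein Ubiquitination Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the comparative evolution of protein
    ubiquitination sites. Estimates Poisson-corrected evolutionary distances
    of modified lysines and of their flanking-region backgrounds across an
    ordered ladder of reference organisms, contrasts the two with z-scores
    and a chi-square combination, compares functional categories through
    relative Poisson distances, scores tissue-expression specificity by
    relative entropy, classifies interaction-network hubs, times the gain of
    sites along the phylogeny, and tests hypergeometric functional
    enrichment of gained-site proteins. A synthetic-data generator with
    recorded ground truth makes every stage testable without external
    databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
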