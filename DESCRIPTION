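Package: bcaudit
Title: Species-Discrimination Audits for DNA Barcode Reference Libraries
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate how well a curated COI barcode reference
    library discriminates species. Computes pairwise Kimura 2-parameter
    distances with pairwise deletion, builds neighbour-joining trees,
    classifies every species' diagnosability (monophyly, haplotype sharing,
    paraphyly/polyphyly/overlap), detects deep intraspecific splits at a
    divergence threshold, summarises the barcode gap, and tests for
    sampling bias by regressing intraspecific divergence on sample size.
    Includes a seeded COI community simulator with ground-truth labels so
    the whole pipeline can be validated without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    jsonlite,
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
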