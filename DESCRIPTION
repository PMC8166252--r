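Package: primsel
Title: Branch-Site Screens for Positive Selection in Primate Gene Regulatory Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting episodic positive selection
    in primate protein-coding genes, with an emphasis on gene regulatory
    factors. Implements ortholog-set curation (read-through and recent-duplicate
    filtering, representative-isoform selection, identity-based ortholog
    clustering, species-tree pruning), codon alignment by protein-guided
    back-translation, GY94-style codon substitution models with branch-site
    mixtures, likelihood-ratio tests for selection on a foreground branch
    (a CODEML Model A style test and a simplified aBSREL-style per-branch
    test), Bayes empirical Bayes and MEME-style per-site detection of
    positively selected sites, two-method consensus, and a verification
    cascade that screens candidate sites against modern-human polymorphism,
    linkage disequilibrium, archaic-human genotypes and great-ape panel
    variation. A synthetic-data generator produces codon alignments evolved
    under branch-site mixtures, population variant tables with controlled
    allele frequencies and LD structure, and archaic/ape genotype tables.
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
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
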