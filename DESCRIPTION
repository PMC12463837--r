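Package: lexstrat
Title: Language-Based Population Stratification from Lexical Distances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes normalized Levenshtein distance (LDN) matrices from
    gloss-aligned multilingual wordlists and recovers population structure
    from them: classical multidimensional scaling, hierarchical clustering
    and neighbor-joining trees.  Provides Mantel permutation tests (with a
    gloss-level bootstrap confidence interval) for comparing lexical,
    genetic (pairwise F_ST) and geographic distance matrices, and greedy
    maximin / cluster-medoid selection of representative language varieties
    for genomic sampling, including a score for "bridge" varieties whose
    lexicon is intermediate between language families.  Includes a seeded
    synthetic-wordlist generator with known family structure for validating
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    stats,
    stringi,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    geosphere,
    jsonlite,
    mclust,
    phangorn,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
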