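Package: abbrsim
Title: String Similarity Measures for Abbreviation Full-Form Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clustering the full forms of biomedical abbreviations by
    string similarity. Implements four character- and token-level similarity
    measures (length-normalized Levenshtein edit distance, a Monge-Elkan style
    local alignment score with character equivalence classes and affine gap
    penalties, SoftTFIDF with the Jaro-Winkler secondary similarity, and the
    character-bigram Dice coefficient), a per-character weighted edit distance
    whose 26 insertion/deletion costs are learned by coordinate descent, a
    threshold-sweep evaluation harness (precision/recall/F-measure, PR curves,
    fixed-recall thresholds), a comparison of split versus single-threshold
    matching for chemical and non-chemical names, and a synthetic generator of
    abbreviation full-form benchmark data with gold concept clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
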