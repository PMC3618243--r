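Package: clinner
Title: Clinical Named-Entity Recognition with Structural SVMs, CRFs and
    Unsupervised Word Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A linear-chain tagger for clinical named-entity recognition
    (problem, treatment, test concepts in discharge-summary-style notes),
    trainable either as a structural support vector machine by the
    cutting-plane algorithm or as an L2-penalized conditional random field
    over the same sparse feature representation. Includes BIO and BIESO
    span encodings with lenient decoding, word-level/orthographic/combined
    feature templates, two unsupervised word-representation feature
    families (Brown-cluster bit-path prefixes and random-indexing
    nearest-neighbour thesauri), span-level exact and inexact
    micro-averaged evaluation, paired-system comparison by sentence
    bootstrap plus Wilcoxon signed-rank, and a synthetic clinical-note
    generator with planted distributional structure for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    quadprog,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
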