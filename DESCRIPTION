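Package: fuzzyarchetypes
Title: Fuzzy Archetype Classification of Cell Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Soft classification of multimodal cell-phenotype tables under
    the explicit assumption of a structured continuum between cell types.
    Fits fuzzy c-means partitions with seeded initialization and centroid
    coalescence, sweeps the fuzziness parameter to chart the emergence
    hierarchy of archetypes, assigns per-cell typicality coefficients and an
    archetypal/atypical/edge-cell taxonomy, profiles archetypes by
    membership-weighted statistics with Mann-Whitney and Fisher pairwise
    comparisons, and quantifies feature relevance by column scrambling of
    the clustering cost. Includes a synthetic phenotype-continuum generator
    with known ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mclust,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
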