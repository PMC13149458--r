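Package: filtconn
Title: Group Analysis of Structural Connectomes Under Tractogram Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-level group analysis of weighted structural brain
    connectomes: edge-level inference with threshold-free network-based
    statistics (TFNBS) and permutation family-wise error control, node- and
    whole-brain-level weighted graph metrics (strength, betweenness
    centrality, Onnela clustering, strength assortativity) with
    Benjamini-Yekutieli correction and Cohen's d effect sizes, and
    two-group classification with linear support vector machines and
    message-passing graph neural networks. Includes a synthetic cohort
    generator that emulates paired filtered/unfiltered connectomes with
    planted group effects, so every stage of the analysis can be exercised
    and calibrated without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    e1071,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
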