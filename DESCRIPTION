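Package: caninefc
Title: Graph-Theoretical Analysis of Canine Resting-State Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted functional brain networks from regional fMRI
    time series and compares their topology between groups. Subject-level
    Pearson correlation matrices over a 30-region canine atlas are
    density-thresholded (20-50%), Fisher r-to-z transformed, and summarised
    with weighted graph metrics (strength, characteristic path length,
    global/local efficiency, Onnela clustering, small-worldness against
    degree-preserving rewired null models). Group differences are assessed
    with Mann-Whitney U tests and Benjamini-Hochberg FDR control at the
    global, nodal (anxiety circuit plus control region) and connection
    level, and network features are correlated with C-BARQ behaviour-scale
    scores by Spearman rank correlation. A synthetic-cohort generator
    produces band-limited multi-region time series with prescribed
    group-level connectivity differences and behaviour scores linked to
    network features, so the full pipeline can be exercised and calibrated
    without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
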