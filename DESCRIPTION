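Package: voxnet
Title: Voxel-Based Brain Network Analysis of Multi-Session fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs voxel-wise functional connectivity networks from
    multi-session BOLD fMRI and analyses their topology across cognitive
    states. Gray-matter voxel time series are band-pass filtered and
    cleaned of nuisance signals, all-pairs Pearson correlation matrices
    are thresholded at the connection density implied by the N = K^S
    rule, and binary graphs are summarised by degree, global efficiency
    and local efficiency. The package builds per-subject session
    consistency maps of top-ranked nodes, cross-subject meta maps, maps
    of nodes connected to high-ranking regional nodes, spherical
    region-of-interest statistics, and two-condition by multi-session
    repeated-measures ANOVAs with partial eta squared. A synthetic
    multi-subject, multi-session BOLD generator with planted
    condition-dependent connectivity hubs makes the full pipeline
    testable without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
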