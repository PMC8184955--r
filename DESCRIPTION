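Package: ramanplex
Title: Multiplexed Live-Cell Raman Profiling by Linear Spectral Unmixing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for multiplexed single-cell Raman probe
    panels. Builds a 16-component reference spectral library spanning the
    protein amide (1500-1700 cm-1) and cell-silent (2000-2300 cm-1) windows,
    simulates whole-cell spectra with population heterogeneity, treatment
    fold changes, baseline drift, noise and corrupted outliers, removes
    background and filters outlier cells by a Pearson-correlation rule,
    linearly unmixes each window against the library (least squares or
    non-negative least squares) with per-cell reconstruction-fidelity
    scoring, and runs single-cell analytics: control-normalized population
    summaries, fold-change radar profiles, t-SNE embedding, Gaussian-mixture
    cluster-number selection, correlation heatmaps and inverse-correlation
    network graphs with centrality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    pracma,
    mclust,
    Rtsne,
    igraph,
    yaml,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
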