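Package: vinecmc
Title: Corticomuscular Coupling Networks via Vine Copulas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates corticomuscular functional coupling from multichannel
    EEG and surface EMG recordings. Each channel is filtered with an
    AR(1)+GJR-GARCH(1,1) model with Student-t innovations and mapped to
    uniform margins by the probability integral transform; cross-channel
    dependence is then modelled with a regular-vine (R-vine) copula whose
    tree structure is selected by maximum spanning trees on absolute
    Kendall rank correlations. Thresholded functional networks with graph
    metrics (characteristic path length, clustering coefficient, core
    nodes) are derived from the dependence matrix, alongside a bivariate
    spectral Granger-causality baseline. A synthetic-data generator with
    known vine dependence and GARCH dynamics supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
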