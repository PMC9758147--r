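Package: psmdim
Title: Dimensionality of Convolutional Network Representations Under
    Spurious Color-Label Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying how the dimensionality of a
    convolutional classifier's internal representation depends on the
    statistical structure of its training environment. Colorized digit
    images are built under either a random or a fixed digit-to-color
    assignment; a small convolutional network is trained in each regime and
    its intermediate activations are summarised by principal-component
    dimensionality indices (weight of primary dimensions, weight of
    secondary dimensions under a Kaiser-like eigenvalue threshold, and the
    number of components explaining 90 percent of variance) and by
    activation-intensity contrasts with false-discovery-rate corrected
    two-sample t-tests. Includes a synthetic glyph generator so the full
    pipeline runs without external data, and a reader for the standard IDX
    digit-image format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
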