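Package: glycoatlas
Title: Quantitative Glycan Atlassing from Multiplexed DNA-PAINT Localization Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed DNA-PAINT single-molecule
    localization data of the cellular glycocalyx. Performs fiducial-based
    residual drift correction and channel alignment, polygon region-of-interest
    segmentation, nearest-neighbour-based (NeNA) localization-precision
    estimation, density-based calling of lectin binding sites with temporal
    rejection of unspecific sticking events, first-nearest-neighbour
    peak-distance matrices across channel pairs, construction of glycan
    (GlyCo) classes from binding sites grouped at a 5-nm cut-off with spatial
    densities per square micrometre, and PCA embeddings of per-sample feature
    vectors that separate cellular states. Includes a synthetic multi-channel
    scene generator with full ground truth (planted binding sites, class
    motifs, blinking time series, localization noise, drift, gold-fiducial
    tracks and sticking artifacts) so every stage is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    minpack.lm,
    pracma,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
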