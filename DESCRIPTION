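Package: bpq
Title: Quantification of 3D-Bioprinted Branched Epithelial Cultures
Version: 0.1.0
Authors@R:
    person("bpq", "developers", email = "bpq@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and quantifying Y-shaped
    3D-bioprinted mammary epithelial cell cultures. Provides parametric
    branched structure designs and G-code toolpath generation for
    extrusion bioprinting, skeleton-based partitioning of culture masks
    into tip and trunk sub-regions, quantification of regional growth
    expansion, invasive protrusions (morphological-opening extraction
    with outline-length normalization), Ki67/DAPI proliferation ratios
    and propidium-iodide viability, Hertz-model analysis of AFM
    spherical-indentation curves, a normality-gated two-group comparison
    procedure, and a seeded synthetic-data generator (culture images and
    indentation curves with known ground truth) so that every stage of
    the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
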