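Package: usvmap
Title: Repertoire Mapping and Statistics for Mouse Ultrasonic Vocalizations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for mouse pup ultrasonic vocalization (USV)
    repertoires. Starting from per-syllable frequency contours (or raw
    audio via a simplified multitaper F-test extraction front-end), the
    package computes dynamically time-warped mean-squared-error distances
    between all contour pairs, embeds the distance matrix into a
    two-dimensional repertoire map with t-SNE, estimates per-group density
    maps on a grid, derives a bootstrap significance map of density
    differences with per-cell Gaussian-mixture fits and an entropy-based
    Sidak multiple-comparison correction, labels map regions as step or
    non-step syllable territory, and tests group differences in step
    prevalence with a 2x2 chi-squared test. A seeded synthetic-repertoire
    generator with genotype- and individual-level structure makes every
    stage testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    EBImage
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
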