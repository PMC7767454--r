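Package: herdmove
Title: Movement-Pattern Analysis for GPS-Tracked Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for describing the movement patterns of GPS-tracked cattle
    kept in small paddocks. Reads GPX and CSV fix streams, removes positional
    noise falling outside a paddock geofence, derives per-relocation movement
    variables (step distance, rate of movement, turning angle, linearity
    ratio), segments relocations into behavioural states (resting, traveling,
    foraging) with agglomerative Ward clustering (Lance-Williams update) and
    Hartigan-Wong K-means validated by connectivity, silhouette width and the
    Dunn index, and summarises the result with Spearman correlations,
    repeated-measures ANOVA with animal as the error term and a chi-squared
    homogeneity test. Includes a stochastic herd simulator (three-state
    correlated random walk with diel modulation, paddock confinement, GPS
    error and logger failure) so the whole pipeline can be exercised and
    calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    xml2,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
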