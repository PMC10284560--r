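Package: svtether
Title: Quantitative Cryo-Electron Tomography Morphometrics of Synaptic
    Vesicle Tethering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and measures the molecular bridges that organize
    synaptic vesicles at the presynaptic active zone in cryo-electron
    tomograms. Tethers (vesicle-to-plasma-membrane bridges) and connectors
    (vesicle-to-vesicle bridges) are segmented by hierarchical connectivity
    segmentation over a threshold series; per-vesicle morphometrics
    (distances to the active-zone membrane, geodesic bridge lengths,
    tether/connector counts, layer occupancy profiles, surface
    concentrations) feed a planned-comparison statistical layer. A
    ground-truthed synthetic phantom generator (membrane slab, spherical
    vesicles, curved rod-like bridges, Gaussian noise, missing-wedge
    filtering) makes the whole pipeline testable without tomogram data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    generics,
    yaml,
    bio3d,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
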