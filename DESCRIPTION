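Package: canopygain
Title: UAV Point Clouds to Genetic Gain for Conifer Breeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end analysis pipeline for drone-photogrammetry
    point clouds of conifer progeny trials. Classifies ground points with a
    cloth-simulation filter, interpolates digital terrain models by
    k-nearest-neighbour inverse-distance weighting, normalises canopy height
    models, detects treetops with a variable-radius local-maximum window,
    delineates crowns by seeded region growing, predicts diameter at breast
    height from height and crown area with a penalized additive model,
    converts diameter and height to above- and belowground biomass through
    power-law allometry, and estimates family variance components by
    restricted maximum likelihood to obtain narrow-sense heritability,
    genetic correlations, family breeding values and realized genetic gain
    under truncation selection. A synthetic-trial generator renders breeding
    trials with known genetic architecture as raw point clouds so the whole
    chain is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    mgcv,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
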