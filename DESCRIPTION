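Package: nanostripe
Title: Coarse-Grained Dynamics and Analysis of Charged Chains on Patterned 2D Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Brownian-dynamics simulation and trajectory analysis for a
    discrete worm-like chain adsorbed on a two-material planar surface, such
    as single-stranded DNA on a graphene/h-BN in-plane heterostructure.
    Provides the chain/surface/field energy model with analytic forces, an
    overdamped Langevin integrator with scenario presets (free diffusion,
    boundary crossing, nanostripe confinement, field-driven transport),
    estimators for persistence length via tangent correlations, diffusion
    constants via windowed mean-squared displacement, drift velocity,
    electrophoretic mobility and Einstein-relation effective charge, Manning
    condensation and nanochannel confinement theory (de Gennes and Odijk
    extensions with regime classification), plus XYZ trajectory input/output
    with provenance sidecars and YAML run configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
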