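Package: intertrack
Title: Intertrack Recombination in Water Radiolysis by Track-Structure
    Reaction-Diffusion Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Step-by-step Brownian reaction-diffusion simulation of the
    heterogeneous chemical stage of water radiolysis (1 ps to 1 us) for
    pairs of ion tracks separated in space (dx) and time (dt). A parametric
    track surrogate produces 1-ps inventories of the radiolytic species
    (OH, e-aq, H3O+, H, H2, H2O2, OH-); a compiled Brownian dynamics engine
    with Smoluchowski reaction radii evolves them with an adaptive timestep;
    delayed tracks are frozen until their arrival and then activated with a
    timestep reset. Yields are reported as time-dependent G-values and as
    normalized 1-us G-value differences against the non-interacting (NI)
    two-track reference, over grids of spatial and temporal separation, with
    replicate uncertainties and significance tests. Intended for studying
    intertrack effects at ultra-high (FLASH) dose rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
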