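Package: dpdnano
Title: Dissipative Particle Dynamics of PLA Nanoparticle Self-Assembly and
    Drug Encapsulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A mesoscale dissipative particle dynamics (DPD) toolkit for
    studying the nanoprecipitation of poly(lactic acid) nanoparticles and
    their loading with amphiphilic lipopeptides (Pam1CSK4, Pam3CSK4) and
    hydrophobic small molecules (vitamin E).  Provides the coarse-grained
    bead scheme and molecule templates, the Flory-Huggins to DPD repulsion
    parameter pipeline with shipped interaction matrices, builders for
    concentrated-solution, droplet-nanoprecipitation and slab-saturation
    geometries, a cell-list DPD integrator with the Groot-Warren thermostat,
    and trajectory analysis covering micelle detection, diameter and
    morphology classification, nanoparticle contraction, radial ordering of
    amphiphiles, water exclusion and encapsulated-fraction estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
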