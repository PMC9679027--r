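Package: metawebsim
Title: Spatial Eco-Evolutionary Meta-Community Food-Web Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assembles trait-based trophic meta-communities on a lattice of
    habitat patches by interleaving allometric population dynamics, adaptive
    foraging with a ratio-dependent functional response, decline-triggered
    dispersal, and speciation from a single founder species. Provides a
    perturbation laboratory (species deletion, whole-network invasion,
    pulse and press patch disruption, sequential disruption with
    nature-reserve schemes), community and species descriptors
    (shortest-chain trophic levels, connectance, omnivory, species ranges),
    species-area curves, and extinction-event-size distribution fits,
    together with versioned text snapshots and a small command-line driver.
License: MIT
Encoding: UTF-8
Imports: Rcpp, jsonlite, stats, utils, tools, graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
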