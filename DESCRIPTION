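Package: larvathermo
Title: Larval Thermotaxis Analysis and Cross-Inhibition Agent-Based Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for larval thermotaxis assays on patchy thermal
    gradient arenas: thermal-camera spike smoothing and gradient quality
    control, track cleaning and staged fragment joining, an electivity-style
    temperature-preference index scored against a random-movement null,
    fine-scale navigation metrics (windowed velocity, tortuosity, head
    sweeps), a cross-inhibition run-and-turn thermotaxis simulator,
    approximate Bayesian computation rejection-sampling fits of homeostatic
    set point and sensitivity slope, and Brownian-motion phylogenetic
    post-processing (ancestral states, lineage shifts, simulation-based
    phylogenetic ANOVA). Includes a synthetic-data generator that emulates
    the assay (track fragmentation, larva clashes, non-movers, thermal
    spikes) so the whole pipeline is testable without raw video data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
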