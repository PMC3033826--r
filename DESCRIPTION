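Package: odnet
Title: Organism-Degree Structure of Multi-Organism Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares the metabolic networks of many organisms through the
    organism degree (OD) of each reaction, the number of organisms whose
    metabolism carries it. Builds bipartite metabolite-reaction networks from
    reaction tables, prunes currency metabolites, projects to directed
    reaction-reaction networks, coarse-grains connected same-OD reactions into
    super nodes with a label-reshuffling null model and z-score, profiles
    average OD against distance from the most central reaction, computes the
    two-node same-OD correlation function, and simulates a neutral,
    biochemistry-constrained model of metabolic network growth on a background
    reaction universe. Includes a synthetic-data generator that evolves
    organism reaction sets along a phylogeny by connected gain and loss.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
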