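Package: allonet
Title: Dynamic Residue Networks and Allosteric Pathways from Protein
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Locates dynamic networks and allosteric pathways that predict
    where distal site-mutations alter protein structure. Computes dynamical
    cross-correlation matrices (DCCM) from conformational trajectories,
    builds contact-filtered correlation-weighted residue graphs and extracts
    shortest-path allosteric pathways, profiles betweenness centrality and
    reachability on Cbeta contact networks, and implements a COREX-style
    ensemble allosteric model (folding-unit state enumeration, residue
    stability constants, thermodynamic alanine scanning). Includes a
    synthetic-data module that generates helical-bundle structures and
    trajectories with planted correlation structure so every stage is
    testable against analytic ground truth, plus consistency metrics for
    comparing networks across methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
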