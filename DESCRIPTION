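Package: fmbr
Title: Metabolic Network Modularization and Bayesian Network Analysis from
    Constraint-Based Flux Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Investigates how a specific perturbation (such as a gene knockout)
    reorganizes a metabolic network. Samples flux distributions under control
    and perturbed conditions by constraint-based flux analysis with randomized
    experimental constraints reconciled by least absolute deviation, selects
    perturbation-responsive core reactions, groups them into metabolic modules
    by hierarchical clustering of flux-variation patterns, learns local and
    global discrete Bayesian networks (MDL score, tabu search) whose
    representative reactions (chosen by total mutual information) reveal
    directions of influence among modules, and scores reaction essentiality
    by single-deletion flux balance analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
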