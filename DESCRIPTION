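Package: rivnet
Title: Co-Occurrence Network Analysis of Riverine Bacterioplankton Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for molecular-ecological-network analysis
    of bacterioplankton communities along human-impacted rivers. Builds signed
    co-occurrence networks from OTU count tables using an ensemble of four
    association measures (Spearman, Pearson, Bray-Curtis, Kullback-Leibler)
    with permutation significance and Benjamini-Hochberg false-discovery-rate
    control; computes the standard suite of network topology indices, module
    detection, and within-module degree / participation coefficient (zi/pi)
    keystone classification; fits the Sloan neutral community model to
    estimate immigration rates; computes a human-activity-intensity land-use
    index (HAILS); and correlates network properties and keystone taxa with
    environmental variables. Includes a synthetic-data module that generates
    count tables with planted correlation blocks, neutrally assembled
    communities with known migration rates, covarying environmental variables
    and land-use gradients, so every stage is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
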