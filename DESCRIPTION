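Package: warburgDE
Title: Paired Tumor-Normal Expression Analysis of the Extended Warburg
    Effect Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential-expression analysis of curated glucose-metabolism
    pathways (glycolysis, gluconeogenesis, pentose phosphate pathway, TCA
    cycle, serine/glycine synthesis, fructose and glutamine utilization,
    initial fatty acid synthesis) in paired tumor and adjacent-normal
    microarray data. Implements detection-call-aware signed fold changes
    with the negative-reciprocal convention, sign-aware averaging, one-sample
    t-tests on log fold changes, representative probe-set selection,
    hierarchical-clustering sample quality control, overlay of gene summaries
    onto a packaged metabolic network with Cytoscape-compatible exports, and
    a seeded synthetic-data generator so the full pipeline can be exercised
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
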