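Package: commcoal
Title: Cohesion, Mixing-Model and Differential-Abundance Analysis of
    Microbial Community Coalescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for community-coalescence microcosm experiments on
    amplicon-derived OTU tables. Infers community stability from positive and
    negative community cohesion built on null-model-corrected pairwise taxon
    correlations; computes expected coalesced communities under a conservative
    (ratio-weighted) mixing model with Bray-Curtis predictability and
    parent-convergence tests; classifies environmental versus biotic responses
    of taxa with a permutation differential-abundance test under
    Benjamini-Hochberg false-discovery control; and simulates full
    serial-transfer coalescence experiments (two parent communities, planted
    correlation structure, environmentally sensitive taxa, one-time and
    repeated mixing at several ratios) with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
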