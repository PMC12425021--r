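Package: sharpr
Title: Hallmark-Based Network Drug Repurposing for Aging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects hallmark-of-aging modules on a protein-protein
    interaction network, screens drugs by network proximity to those
    modules with degree-matched null significance, and scores each
    proximal drug's directional effect on aging-associated transcription
    with the pAGE sign-concordance statistic. Implements the two-step
    SHARP screening pipeline (proximity filter, then pAGE directionality)
    with confidence-stratified hallmark gene sets, module separation and
    overlap statistics, mechanism traces, validation capture accounting,
    and a synthetic-data generator that plants modules, proximal drugs
    and signature concordance with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
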