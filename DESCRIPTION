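Package: ScaffoldSpace
Title: Pharmacophore-Aware Scaffold Extraction and Combinatorial
    Chemical-Space Enumeration
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for target-focused chemical-space construction from
    docked 3D poses: perception of pharmacophore features and geometric
    matching against user-defined 3D hypotheses, extraction of primary
    scaffolds by retrosynthetic (BRICS-style) fragmentation gated by key
    pharmacophore points, harvesting of left/right peripheral fragments,
    combinatorial expansion of trivalent scaffolds, implicit
    Cartesian-product library counting with exact integer arithmetic,
    streaming enumeration and seeded sub-sampling, structural-alert
    (medicinal chemistry filter) screening, constant-reward-value and
    similarity-penalty reward shaping for generative loops, and
    virtual-hit-rate extrapolation statistics with Wilson intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
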