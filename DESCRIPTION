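Package: wwbenthos
Title: Trait-Based Analysis of Stream Invertebrate Responses to Wastewater
    Point Sources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing benthic macroinvertebrate community change
    below wastewater treatment plant outfalls in a replicated
    upstream/downstream (BACI-style) design. Computes taxonomy- and
    trait-based community descriptors (Saprobic Index, SPEAR pesticides
    index, EPT metrics, diversity indices), null-corrected change statistics
    including a Total Community Change index in NMDS space, wastewater
    dilution factors and PCA-derived disturbance predictors, a constrained
    and unconstrained ordination suite (Hellinger transform, NMDS,
    PERMANOVA, partial RDA, PCNM, variation partitioning, forward
    selection), and hierarchical partitioning with randomization Z-scores.
    Includes a calibrated synthetic-data generator emulating a twelve-stream
    wastewater disturbance gradient for power analysis and end-to-end
    pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vegan,
    permute,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
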