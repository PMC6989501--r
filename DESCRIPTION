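Package: plasticome
Title: Gut Microbiota Plasticity and Longitudinal 16S Community Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying per-subject gut microbiota plasticity from
    longitudinal 16S rRNA amplicon sequence variant (ASV) tables:
    consecutive-day and cross-period beta-diversity plasticity statistics,
    five bounded beta-diversity metrics (Bray-Curtis, Jaccard, Jensen-Shannon,
    unweighted and normalized weighted UniFrac), rarefaction-interpolated
    phylogenetic alpha-diversity, phylogenetic tree-cut clustering of ASVs,
    a variance-stabilized moderated differential-abundance stack (poscounts
    size factors, inverse-hyperbolic-sine voom-style precision weights,
    consensus within-subject correlation, empirical-Bayes moderated
    t-statistics), Prevotella/Bacteroides ratio classification, ordination
    and PERMANOVA, and a synthetic-cohort generator emulating a two-arm
    diet-intervention sampling design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    phyloseq,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
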