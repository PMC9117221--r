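Package: micromatch
Title: Matched-Control Subsampling and Compositional Analysis for
    Microbiome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for cross-sectional amplicon microbiome
    cohorts with unbalanced group sizes: repeated matched-control
    subsampling balanced on age, gender and region; multivariate testing in
    Aitchison geometry (PERMANOVA, homogeneity of dispersion about spatial
    medians, analysis of similarities over family and classroom units);
    consensus differential-abundance trend models across age with type-II
    ANOVA and false-discovery-rate aggregation; sparse co-occurrence
    network inference with a pairwise network-uniqueness score; and a
    synthetic cohort generator with planted compositional effects for
    validating the whole stack.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ape,
    picante,
    phyloseq,
    car,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
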