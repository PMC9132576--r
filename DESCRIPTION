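Package: T2DMAging
Title: Matched-Cohort Analysis of Accelerated Brain Aging in Type 2 Diabetes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether type 2 diabetes mellitus (T2DM)
    accelerates brain aging. Implements eligibility filtering and exact
    pairwise case-control matching of cohort tables; linear-model effect
    estimation for cognitive domains and 45 bilateral gray-matter regions,
    expressed as percent of matched healthy-control means with Bonferroni or
    Benjamini-Hochberg correction; amplitude of low-frequency fluctuation
    (ALFF) maps from 4D resting-state volumes with global-mean normalization,
    Gaussian smoothing, voxelwise group statistics and FDR plus
    cluster-extent thresholding; Pearson overlap of T2DM and age effect maps;
    a Fieller-theorem confidence interval for the duration-slope to age-slope
    acceleration ratio; and a random-effects standardized-mean-difference
    meta-analysis across cognitive domains. A synthetic-cohort module
    generates demographics, regional volumes, cognitive scores and
    band-limited fMRI signals with known ground truth so every stage is
    testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    metafor,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
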