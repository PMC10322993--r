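Package: morphogene
Title: Case-Control Brain Morphometry Effect Maps and Imaging-Transcriptomic Null Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regional case-control neuroimaging analysis of genetic
    syndromes: Cohen's d effect-size maps of cortical and subcortical
    morphometry with ANCOVA and residualized t-test routes, a label-permutation
    test for spatial convergence of two genotype effect maps, an atlas-style
    probe-to-region gene-expression aggregation chain, gene-brain correlation
    tested against spatial spin, random-gene and brain-gene null models, and
    brain-behavior correlation decoupling tests with Fisher r-to-z comparisons
    and Benjamini-Hochberg FDR. Includes seeded synthetic-data generators
    (cohort, spherical parcellation, transcriptome, behavior scores) with
    programmable ground truth so every stage is testable without restricted
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
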