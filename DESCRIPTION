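Package: magniche
Title: Predicting Microbial Ecological Niches from Genome Content
Version: 0.1.0
Authors@R: person("Baltic", "Binner", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for linking the gene content of metagenome-assembled
    genomes (MAGs) to their ecological niches. Builds species-level genome
    clusters from average nucleotide identity, derives orthologous-group
    gene profiles and coverage-based abundance profiles, constructs a
    "virtual niche space" by principal coordinates analysis with Cailliez
    correction, predicts niche placements from gene content with
    cross-validated ridge regression, random forests and gradient boosting
    or from phylogeny with Brownian-motion ancestral-state estimation, and
    compares ecology-gene-content against ecology-phylogeny signal with
    (partial) Mantel permutation tests. Includes a fully parameterised
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
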