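Package: germnet
Title: Germline Variation Network Analysis for Familial Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("GermNet", "Developers", email = "germnet@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for germline-variation network analysis in
    familial cancer case-control studies: Fisher-exact single-nucleotide
    variant calling from per-position pileups, refFlat-based coding
    consequence annotation, protein-protein interaction main-graph
    statistics with power-law degree-distribution fits, hypergeometric
    pathway enrichment, a two-feature linear support-vector risk
    classifier, and crude odds-ratio epidemiology with Woolf confidence
    intervals. Includes a seeded synthetic-data generator producing every
    input the pipeline consumes (genomes, gene models, pileups with
    planted variants, scale-free interaction networks with a planted
    module, pathway files, and case-control cohorts), so all stages are
    testable without access to patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
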