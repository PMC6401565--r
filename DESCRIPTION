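Package: metrwr
Title: Metabolite Prioritization on Heterogeneous Gene-Metabolite-Phenotype
    Networks by Random Walk with Restart
Version: 0.1.0
Authors@R: person("metrwr", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds a weighted heterogeneous network from six edge sets
    (gene-gene, metabolite-metabolite, phenotype-phenotype, gene-metabolite,
    gene-phenotype, metabolite-phenotype), seeds it with disease genes, a
    disease phenotype and differentially expressed genes called by per-gene
    t-tests with Benjamini-Hochberg FDR control, runs random walk with
    restart over a column-stochastic transition model, and ranks candidate
    metabolites by proximity to the seeds. Includes a synthetic-data
    generator with planted ground truth for end-to-end testing, subnetwork
    extraction and degree (hub) reporting, and a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
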