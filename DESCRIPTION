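Package: metdep
Title: Explaining Cancer Cell-Line Dependencies on Metabolic Genes
Version: 0.1.0
Authors@R: person("metdep", "maintainers", email = "maintainers@metdep.dev", role = c("aut", "cre"))
Description: Analyses cell line-specific essentiality of metabolic genes from
    genome-scale genetic screens (RNAi/CRISPR dependency scores). Derives
    functional relatedness (neighboring enzymes and isozymes) from a
    genome-scale metabolic network with currency-metabolite filtering,
    tests culture-media confounding of dependency scores with rank-based
    and partial-correlation statistics, correlates dependencies with the
    expression of functionally related enzymes against shuffled-set nulls,
    and fits permutation-calibrated random-forest models of per-gene
    dependency from molecular, media and lineage features. Includes a
    synthetic screen generator with plantable ground-truth effects so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
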