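Package: neamix
Title: Network Enrichment Analysis for Multi-Omics Cancer Genomics
Version: 0.1.0
Authors@R:
    person("neamix", "maintainers", email = "neamix@example.org", role = c("aut", "cre"))
Description: Integrative analysis of altered gene sets in gene networks.
    Implements network enrichment analysis (NEA) of altered gene sets
    (single-nucleotide variants, copy-number alterations, allelic imbalance)
    against functional gene sets, with a degree-preserving edge-swap
    randomization null, direct and indirect (shared-neighbor) link statistics,
    left-tail and random-gene-set false discovery rates, and a hypergeometric
    gene-set enrichment comparator. Includes the genomic filtering stages that
    precede the network analysis (copy-number/expression/protein correlation
    filters with permutation control, allelic-imbalance calling from DNA/RNA
    allele depths, damaging-SNV set construction), calibrated synthetic-data
    generators with planted ground truth, and a deterministic end-to-end
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
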