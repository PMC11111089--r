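Package: gpnet
Title: Genotype-Phenotype Network Construction and Module-Based Multi-Trait
    Association Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a signed bipartite genotype-phenotype network (GPN) from
    individual-level GWAS data or from summary statistics, using score tests
    with saddlepoint-approximated p-values for binary traits with extremely
    unbalanced case-control ratios. The network is projected onto phenotypes
    to obtain a signed genetic-correlation network, phenotypes are
    partitioned into disjoint modules by Ward clustering with a
    perturbation-calibrated choice of the module count, and per-SNP
    multi-phenotype association tests (O'Brien, Omnibus, CLC, ceCLC, HCLC,
    MultiPhen) are run per module with Bonferroni combination across
    modules. Includes a factor-model phenotype simulator with liability
    thresholding and a Monte-Carlo harness for type-I-error and power
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
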