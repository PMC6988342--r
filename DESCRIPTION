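Package: gutnet
Title: Integrated Host Gene-Microbiome Correlation Networks for Mucosal 16S and RNA-seq Count Data
Version: 0.1.0
Authors@R:
    person("Maintainer", "Anonymous", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative analysis toolkit for paired host transcriptome and
    mucosal 16S microbiome count tables. Provides prevalence-based contaminant
    screening against negative controls, rarefaction-based alpha diversity with
    group testing, beta diversity (Bray-Curtis and UniFrac) with PCoA and
    PERMANOVA, a simplified negative-binomial Wald and likelihood-ratio test for
    differential abundance shared between genes and taxa, taxonomic
    agglomeration and prevalence/abundance filtering, a centered log-ratio
    Spearman screen of gene-taxon pairs with Storey q-value control, a
    from-scratch SparCC estimator of compositional microbe-microbe correlations
    with permutation pseudo p-values, and assembly/export of the mixed
    gene-taxon network. Ships a synthetic-data generator with planted ground
    truth so every stage can be validated against a known answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
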