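Package: funtaxa
Title: Function-by-Taxon Profiling and Attribution for Metagenome Gene
    Catalogs
Version: 0.1.0
Authors@R:
    person("Rumen", "Metagenomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning an annotated non-redundant metagenome gene
    catalog and per-sample mapped-read counts into transcripts-per-million
    (TPM) abundance profiles at taxonomic ranks and functional schemes
    (KEGG Orthologs, CAZy families and classes, hydrogenase categories),
    for two-group differential testing of those profiles with Wilcoxon
    rank-sum tests and tiered significance calls, for permutation-based
    community statistics (Bray-Curtis PCoA, PERMANOVA, ANOSIM, multivariate
    dispersion) implemented from first principles, and for a genus-level
    contribution decomposition that attributes each differential functional
    feature to the microbial genera driving the between-group change. A
    synthetic-data module simulates an annotated catalog and overdispersed
    count matrix for a two-group cohort with planted effects so that every
    stage of the pipeline can be exercised and verified without access to
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
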