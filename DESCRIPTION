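Package: colonyIGV
Title: Intracolonial Genetic Variability from Replicate Microsatellite Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects intracolonial genetic variability (IGV) in colonial
    organisms from replicate-sampled (nubbin) microsatellite multilocus
    genotypes, and partitions it into mosaicism versus chimerism using two
    mutation-model distances: the number of different alleles (infinite
    allele model) and Bruvo's distance (stepwise mutation model). Decision
    thresholds are derived from the data themselves: a minimum number of
    comparable loci via an exact combinatorial false-negative analysis of
    locus removal, and mosaic/chimera cutoffs at the first antimode of the
    pairwise distance distributions. Includes readers and writers for
    genotype tables, a ground-truthed synthetic colony generator for
    validation, per-stratum category summaries and Fisher exact
    homogeneity tests, and a single-call pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'accessors.R'
    'genotype-io.R'
    'distances.R'
    'thresholds.R'
    'classify.R'
    'synthetic-data.R'
    'report.R'
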