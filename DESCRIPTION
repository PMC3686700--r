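Package: fsgwas
Title: Family-Based Genome-Wide Association Analysis with Realized
    Relationship Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide association analysis in full-sib family
    populations such as those produced by factorial mating designs in fruit
    breeding. Builds pedigree-expected (A) and marker-realized (VanRaden G)
    relationship matrices, fits single-kinship linear mixed models by
    restricted maximum likelihood using a one-time eigendecomposition,
    reports a likelihood-ratio measure of variance explained, runs
    EMMAX-style single-SNP association scans with BIC-selected principal
    component covariates, back-solves SNP allele substitution effects from
    genomic breeding values, decomposes breeding values to linkage-group
    level for genetic correlations, profiles linkage disequilibrium decay,
    and computes analytic power of marker-trait association tests under
    cryptic relatedness. Includes a synthetic-data generator emulating a
    factorial full-sib mating design with linkage, pollen contamination and
    pleiotropic multi-trait architectures, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
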