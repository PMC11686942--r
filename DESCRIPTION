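Package: matwealth
Title: Heritability of Material Wealth in Spatially Structured Bird Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for studying how access to
    fitness-relevant resources ("material wealth", e.g. caterpillar biomass in a
    breeding territory) becomes heritable in wild populations. Provides a
    Gaussian-random-field landscape generator with controlled spatial
    autocorrelation and between-year persistence, an individual-based simulator
    of a philopatric nest-box population with Mendelian genotypes, pedigree and
    in-silico cross-fostering, pedigree (A) and genomic (VanRaden G) relatedness
    matrices with LD pruning, variance-component estimation by average-information
    REML and Haseman-Elston regression (animal models with permanent-environment
    and year effects, repeatability with parametric bootstrap), a repeated-measures
    mixed-model GWAS with Wald tests, SNP-to-gene window mapping with hypergeometric
    gene-set over-representation, and the landscape analyses that separate genetic
    from philopatry-driven inheritance of wealth: natal-versus-breeding wealth
    similarity by dispersal distance, cross-fostering contrasts, and a
    distance-preserving spatial null simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
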