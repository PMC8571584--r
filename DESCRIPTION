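Package: seqpopgen
Title: Multilocus Sequence Population Genetics for Phylogeography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multilocus Sanger-type sequence data for
    phylogeographic studies of structured populations: per-locus and
    per-population diversity statistics (segregating sites, haplotype and
    nucleotide diversity), Tajima's D and Fu's Fs neutrality tests with
    coalescent-simulation p-values, hierarchical analysis of molecular
    variance (AMOVA) with Phi- and F-statistics and permutation tests,
    pairwise differentiation matrices and Mantel isolation-by-distance
    tests, sex-biased dispersal inference (per-sex F_IS, maximum-likelihood
    pairwise relatedness, bootstrap difference-of-means test), and
    approximate Bayesian computation (ABC) scenario choice for population
    colonization histories via coalescent simulation, rejection sampling,
    linear discriminant projection and weighted multinomial logistic
    regression. Includes a coalescent-based synthetic-data generator that
    emulates a multi-ocean seabird sampling design with known truth for
    calibration and power analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    nnet,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
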