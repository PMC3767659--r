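Package: sociogen
Title: Sociogenetic and Population-Genetic Analysis of Ant Colonies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for colony-level sociogenetics and population genetics of
    social insects. From colony-structured microsatellite genotype tables and
    aligned mitochondrial sequences, the package reconstructs queen genotypes,
    partitions workers into patrilines, estimates absolute and effective queen
    mating frequencies with non-detection probabilities, computes
    Queller-Goodnight relatedness with jackknife errors, Weir-Cockerham
    F-statistics, exact Hardy-Weinberg and linkage-disequilibrium tests under
    a one-individual-per-colony resampling design, Mantel isolation-by-distance
    and Clark-Evans nearest-neighbour spatial tests, haplotype collapsing,
    median-joining networks and hierarchical AMOVA. A synthetic-data generator
    produces monogynous, polyandrous colonies, mapped nest plots and
    two-group mitochondrial transects so that every stage is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
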