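Package: mlsapop
Title: Population Structure Analysis from Multilocus Sequence Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.net", role = c("aut", "cre"))
Description: Tools for multilocus sequence analysis (MLSA/MLST) of bacterial
    populations: allele calling from per-locus alignments, sequence-type
    assignment, per-locus heterogeneity and Nei-type genetic diversity,
    the standardized index of association with Monte-Carlo significance,
    single-locus-variant enumeration with mutation/recombination
    classification, AMOVA-based pairwise F_ST with permutation tests, and a
    Spearman Mantel test for isolation by distance.  Ships the published
    Thermoanaerobacter uzonensis hot-spring dataset as a worked fixture and
    a forward-time haploid multi-deme simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
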