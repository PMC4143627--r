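Package: admixscan
Title: Admixture Mapping and Ancestry-Adjusted Association Scans for Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for admixture mapping in recently admixed populations.
    Simulates three-way admixed cohorts (European/African/Native-American-like)
    with known local-ancestry tracts, genotypes drawn from ancestral allele
    frequencies and blood-pressure-like traits; selects ancestry-informative
    markers by pairwise Fst thresholds with greedy LD pruning; estimates the
    number of generations since admixture from ancestry-segment counts; runs
    per-SNP ancestry-deviation regression scans and genotype association
    scans adjusted for local ancestry, with Benjamini-Hochberg FDR, genomic
    control and a permutation excess-signal test; and computes case-control
    power under a dominant penetrance model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml, vcfR
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
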