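Package: hyblineage
Title: Detection and Classification of Incipient Hybrid Lineages from SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting and characterising young homoploid hybrid
    lineages from multi-sample SNP genotype data. Implements diagnostic-marker
    discovery (private high-frequency alleles, fixed differences, relaxed
    frequency-contrast panels), maximum-likelihood hybrid indices and joint
    ancestry/interclass-heterozygosity estimation on the (S,H) triangle with
    generation-class assignment (parental, F1, F2, first-generation backcross,
    later-generation hybrid), a phylogenetic-invariants hybridization test with
    gamma estimation and block-jackknife significance, SNP quartet concordance
    factors, windowed Weir & Cockerham Fst, genotype PCA, and a forward-time
    Wright-Fisher simulator of a two-parent admixture demography (population
    samples plus explicit F1/F2/backcross pedigrees) for validating every
    stage against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
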