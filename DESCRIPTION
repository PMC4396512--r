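Package: glucotype
Title: Glucosinolate Pathway Genetics, Haplotype Inference and Field Fitness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for connecting natural variation in the Arabidopsis thaliana
    aliphatic glucosinolate (GSL) pathway to leaf chemical profiles, multi-locus
    haplotype frequencies and field fitness. Provides a rule-based forward model
    from multi-locus GSL genotypes to predicted leaf profiles, an inverse
    haplotype caller with epistasis-aware unobservability, a linkage-equilibrium
    test of multi-locus haplotype frequencies with Monte-Carlo calibration,
    fitness and normalization computations for field trials, a split-plot
    linear mixed model with Type II sums of squares, LSMeans and Dunnett/Tukey
    comparisons, PCA-based concordance of profiles across environments, and a
    synthetic-data generator that emulates the split-plot field design and
    accession panels so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), lme4, car, emmeans, multcomp, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
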