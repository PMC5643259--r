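Package: pedflow
Title: Family-Based Genetic Analysis of Large Multiplex Disease Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for family-based genetic studies of large multiplex
    pedigrees with a complex disease: pedigree construction and kinship
    (pedigree-derived and genotype-derived), genotype quality control with
    Mendelian-error zeroing and deterministic fill-in, genetic risk scores
    from known risk loci with simulated case/control reference
    distributions, affected-only parametric linkage via the Lander-Green
    inheritance-vector hidden Markov model, haplotype-flow reconstruction
    with divide-and-conquer pedigree splitting and IBD-guided reassembly,
    within-family rare-variant imputation from the reconstructed flow,
    kinship-adjusted mixed-model association with a Wald test, an exome
    variant prioritization cascade, and a synthetic pedigree generator so
    every stage can be validated end-to-end against simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
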