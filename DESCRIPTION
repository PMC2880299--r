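Package: phasebias
Title: Haplotype Phasing Confidence and the Bias from Omitting Unresolved
    Genotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates phase-known diploid nuclear sequence datasets under a
    neutral Kingman coalescent with HKY85 sequence evolution, collapses them
    into IUPAC ambiguity-coded genotypes, re-resolves gametic phase with a
    Bayesian Gibbs sampler that reports per-individual confidence
    probabilities, and quantifies what the common practice of discarding
    below-threshold (unresolved) genotypes does to downstream phylogeographic
    inference: haplotype-pair error taxonomies, lost alleles and their
    divergence skew, systematic bias in Watterson's theta, nucleotide
    diversity, Tajima's D and Fu's F_S, and root changes in statistical
    parsimony haplotype networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, PopulationGenetics, Coalescent, Software
RoxygenNote: 7.3.3
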