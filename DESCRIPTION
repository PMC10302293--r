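Package: cherrypop
Title: Haplotype-Based Phylogeography and Demographic Inference for Cherry
    Accession Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for sequence-based phylogeography of cherry
    (Prunus) accession panels genotyped at nuclear ITS and chloroplast loci.
    Reads aligned FASTA plus population metadata, recodes indels as binary
    characters, collapses sequences into haplotypes, and computes alignment
    summaries, gene and nucleotide diversity, Tajima's D and Fu's Fs with
    coalescent-simulated p-values, mismatch-distribution sudden-expansion
    fits with parametric-bootstrap significance, hierarchical AMOVA with
    Phi-statistics and permutation tests, pairwise Phi-ST matrices,
    Tamura-Nei (1993) distances, and median-joining haplotype networks.
    A structured-coalescent scenario simulator generates synthetic accession
    panels under two-epoch divergence histories with optional admixture, and
    an approximate Bayesian computation layer performs scenario choice by
    rejection plus multinomial logistic regression, parameter estimation
    with local-linear adjustment, and confusion-matrix error assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    nnet,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
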