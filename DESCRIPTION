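Package: mhctsp
Title: Trans-Species Polymorphism Analysis of MHC Class IIB Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and dating trans-species allelic lineages in
    major histocompatibility complex (MHC) class IIB exon 2 amplicon data.
    Implements replicate-validated amplicon genotyping, modified Nei-Gojobori
    dN/dS with the codon Z-test for positive selection, Tajima's D, an
    entropy-based substitution-saturation index, neighbor-joining trees with
    nonparametric bootstrap support, detection of supported multi-genus
    allelic lineages, a functional-constraint-adjusted substitution rate
    (regression of synonymous on total pairwise divergence within a lineage,
    scaled by a neutral genomic rate), and Bayesian MCMC divergence dating
    under HKY+Gamma with strict, random-local and relaxed-exponential clocks.
    A coalescent gene-duplication simulator generates replicated amplicon
    reads with point errors and PCR chimeras so the whole pipeline runs on
    data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    Matrix,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
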