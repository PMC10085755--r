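Package: mutsfs
Title: Mutation-Subtype-Resolved Analysis of the Site Frequency Spectrum
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Partitions biallelic SNVs into the 96 strand-collapsed 3-mer
    mutation subtypes, builds unfolded per-subtype allele frequency spectra,
    and quantifies heterogeneity across subtypes with Tajima's D and a
    singleton/doubleton-free analogue (D-2) whose analytic variance is
    derived from neutral-coalescent covariances of spectrum entries. Also
    estimates per-subtype mutation rates from singleton densities with a
    de-novo-mutation normalization, fits single-population growth and
    three-epoch demographic models to spectra by Poisson composite
    likelihood, relates regional subtype composition to local spectrum
    statistics with generalized estimating equations, and generates fully
    synthetic genomes (FASTA/VCF/BED/tracks) with known ground truth for
    validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Biostrings,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    dplyr
Config/testthat/edition: 3
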