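Package: glpop
Title: Genotype-Likelihood Population Genetics for Low-Coverage Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for low- and medium-coverage resequencing
    data that works on genotype likelihoods instead of called genotypes.
    Reads multi-individual samtools-style text pileups and BEAGLE genotype
    probability files; computes per-individual genotype likelihoods (GATK-style
    independent-reads model and a type-specific error-matrix model); estimates
    population minor allele frequencies by EM and tests sites for variability
    with a likelihood ratio test; computes sample-allele-frequency (SAF)
    likelihoods by dynamic programming and estimates one- and two-population
    site frequency spectra by EM; calls genotypes under uniform,
    allele-frequency and SFS priors; computes ABBA-BABA D-statistics from
    single sampled bases with a weighted block jackknife; estimates
    type-specific base error rates; and includes a seedable simulator of
    diploid pileup data (Poisson depth, symmetric base error, configurable
    site frequency spectrum) so every stage can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
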