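Package: jfblup
Title: Single-Step SNPBLUP with Breed-Specific J-Factor Covariates for
    Crossbred Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic evaluation of three-way crossbred populations with
    single-step SNPBLUP, fitting zero, one, or breed-specific J-factor
    covariates that model the mean of genotyped animals when SNP genotypes
    are centred at observed rather than base-population allele frequencies.
    Provides pedigree numerator-relationship algebra, direct and
    ancestor-restricted computation of J-factor covariates from pedigree
    expected or observed breed fractions, construction of the single-step
    relationship matrix, Henderson mixed-model equation and SNP-level
    solvers, cross-validation with random or phenotype-based selective
    genotyping, weighted validation statistics (accuracy and dispersion
    bias of sire breeding values), and a gene-dropping simulator of
    three-way crossbred populations for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
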