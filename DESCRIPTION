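Package: varcall
Title: Integrated Bayesian Germline and Somatic SNV/Indel Calling from Pileup Columns
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated caller for germline and somatic single-nucleotide
    variants and short insertions/deletions operating on per-site pileup
    columns. Germline genotypes are inferred from a multinomial allele-count
    likelihood combined with mutation-rate based genotype priors; called
    variants are graded by a variant confidence score with analytic
    high/low-confidence thresholds. Indels are detected by two Fisher's exact
    tests and their consensus sequence derived by a multiple ungapped
    alignment over a position-specific weight matrix. Somatic variants are
    called from matched tumor-normal pairs by a hybrid of subtraction
    analysis and a joint diploid-genotype posterior, classified into
    Wild/Somatic/LOH/Germline/Unknown types. Includes SAMtools
    pileup/mpileup parsing, VCF output, a synthetic pileup simulator with
    ground truth, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
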