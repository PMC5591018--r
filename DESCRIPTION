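Package: ypal
Title: Mutation and Gene-Conversion Dynamics of Y-Chromosome Palindromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers mutation and gene-conversion events in Y-chromosome
    palindrome arms from pseudo-diploid genotypes placed on a sample
    phylogeny, using Fitch-style ancestral-state reconstruction with
    outgroup polarisation. Quantifies GC and ancestral biases of gene
    conversion, estimates per-position per-generation event rates
    calibrated against X-degenerate SNVs, estimates gene copy numbers
    from normalised median read depth, and scores father-son scaffold
    concordance in windows. Includes a forward simulator of palindrome
    evolution (phylogeny, haploid SNVs, pseudo-diploid genotypes with a
    logged event truth, and coverage tracks) for validating the
    inference under known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    graphics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
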