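Package: carrierfreq
Title: Carrier and Genotype Frequency Estimation for Recessive Disease
    from Population Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the population frequency of autosomal-recessive
    disease genotypes from allele counts observed in large population
    genomic databases.  Parses and validates HGVS cDNA and protein
    variant descriptions, maintains a registry of pathogenic variants
    with per-database, per-population allele counts, pools them into a
    cumulative minor allele frequency (cMAF), and applies the
    Hardy-Weinberg equation to derive expected biallelic (affected) and
    carrier frequencies, "1 in N" reporting figures and expected case
    counts.  Ships a forward simulator that draws diploid cohorts under
    Hardy-Weinberg equilibrium from a set of rare pathogenic alleles
    (including founder-allele scenarios) so that the whole pipeline can
    be validated by parameter recovery.  Bundled fixture tables describe
    pathogenic variants of the APRT gene, whose deficiency causes
    2,8-dihydroxyadenine kidney stones and chronic kidney disease.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
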