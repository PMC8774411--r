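Package: recleth
Title: Screening and Validation of Recessive Lethal Variants Linked to
    Homozygote-Deficient Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and validating recessive juvenile-lethal
    variants linked to homozygote-deficient haplotypes in livestock
    populations. Implements region-restricted genotype-concordance variant
    prioritization from whole-genome sequence calls, a minimal
    transcript-aware consequence engine for stop-gain (nonsense) variants
    with HGVS-style naming, and the validation statistics used in such
    studies: homozygote-deficiency Poisson tests, haplotype-genotype
    association, Hardy-Weinberg and Mendelian segregation tests, allele and
    carrier frequency estimation, exact rank-sum comparisons of growth
    traits, and attributable-mortality estimation. A seeded synthetic
    population generator emulates a carrier-screening study (sequenced
    carrier panel, genotyped cohort with rare discordances, at-risk
    carrier-by-carrier matings) so the whole pipeline runs end-to-end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    vcfR,
    withr
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
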