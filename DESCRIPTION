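Package: lethalscan
Title: Discovery and Validation of Recessive Lethal Haplotypes in Pedigreed Livestock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for mapping recessive lethal alleles segregating in
    intensively pedigreed populations from routinely collected SNP-array
    genotypes and reproduction records. Slides haplotype windows over phased
    genotypes and flags haplotypes with a significant deficit of homozygotes
    under Hardy-Weinberg expectations (exact binomial test), contrasts litter
    survival between carrier-mating classes, prioritizes candidate causal
    variants in sequenced carriers by linkage disequilibrium and predicted
    consequence, translates frameshift indels to protein consequences, checks
    Mendelian segregation and penetrance in genotyped litters, and fits a
    weighted pedigree-based animal model for carrier associations with
    deregressed breeding values. Includes a gene-drop simulator producing a
    pedigreed population segregating a recessive lethal haplotype so the whole
    analysis runs with no external data.
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
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
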