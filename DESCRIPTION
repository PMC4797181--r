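Package: snpsexdiff
Title: Sex-Stratified SNP Association and Sex-Differentiated Effect Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sex-stratified case-control association analysis for candidate-SNP
    panels: genotype quality control (call-rate filtering, minor-allele
    orientation, exact Hardy-Weinberg testing with Bonferroni thresholding,
    between-sex allele-count comparison), per-sex additive logistic regression
    of binary pigmentation/sun-sensitivity traits and melanoma status on
    minor-allele dosage, a sex-differentiated regression estimate test
    (per-sex 1-df Wald chi-squares, their 2-df joint sum, and a 1-df
    heterogeneity test of allelic effects), direction-of-effect enrichment
    comparisons between sexes via 2x2 contingency tables, reanalysis of
    published odds-ratio tables, a synthetic genotype-phenotype study
    generator, and volcano/Manhattan/enrichment graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
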