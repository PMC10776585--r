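Package: fmratio
Title: Female-to-Male Allele Proportion Ratios for Detecting Sex-Specific
    Variant Pathogenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes pseudocount-adjusted female-to-male allele proportion
    ratios from sex-stratified allele counts (delimited tables or
    gnomAD-dialect VCF), calibrates an empirical high-ratio threshold
    against pseudoautosomal variants as a built-in null, flags candidate
    sex-specific-pathogenicity variants on the non-pseudoautosomal X
    chromosome, and reconciles flagged variants with clinical, structural
    and regulatory annotation evidence. Includes a Hardy-Weinberg
    viability-selection simulator for generating gnomAD-style
    sex-stratified cohorts so the statistic's operating characteristics
    can be studied without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
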