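Package: hlaloh
Title: Allele-Specific HLA Loss of Heterozygosity Calling from Paired
    Tumor-Normal Exomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects somatic loss of heterozygosity (LOH) of HLA class I
    alleles from paired tumor-normal exome sequencing. Builds patient-specific
    HLA references from an IMGT-style allele database with exon/intron
    imputation, derives allele-specific b-allele-frequency and sequencing-depth
    features at positions where the two homologous alleles differ, and calls
    LOH with a gradient-boosted classifier followed by post-hoc decision rules
    that assign the deleted allele. Includes an in-silico tumor/normal mixture
    framework for limit-of-detection analysis across tumor purity and clonality,
    and a synthetic fixture generator emulating allele-specific capture bias
    and overdispersed coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    xgboost,
    Biostrings,
    Rsamtools,
    pROC,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    class,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
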