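Package: strataforge
Title: Ancestry Assignment Strategies and Residual Population Stratification in GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how the strategy used to assign individuals of a
    large admixed cohort to ancestry groups changes the residual population
    stratification of downstream genome-wide association studies (GWAS).
    Provides a Balding-Nichols simulator for reference panels and
    longitudinally structured admixed cohorts with a confounded polygenic
    trait; genotype QC and input/output (VCF and dosage tables); reference
    panel principal component analysis with projection, random-forest
    ancestry classification, median-absolute-deviation outlier refinement,
    and a coarse self-identified-label baseline; supervised admixture
    proportion estimation by expectation-maximization; birth-cohort
    construction and comparison statistics; per-group association scans; and
    LD score regression (intercept, heritability, attenuation ratio) with
    block-jackknife standard errors for comparing assignment methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    randomForest,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
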