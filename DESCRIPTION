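Package: trionurture
Title: Within-Family Trio Polygenic-Score Analysis of Genetic Transmission and Genetic Nurture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates genetic transmission from genetic nurture in the
    intergenerational transmission of quantitative child traits using
    mother-father-child trio polygenic scores. Provides a trio cohort
    simulator (Hardy-Weinberg genotypes, optional two-deme stratification
    and assortative mating, Mendelian transmission, phenotypes built from
    direct and parental-nurture paths, noisy GWAS weights, informative
    missingness), polygenic-score construction from summary statistics with
    p-value thresholding and a PRS-PC composite, ancestry-PC residualization,
    RS-DBD item scoring with multiple imputation and Rubin pooling, and the
    unadjusted/trio/across-factor regressions with a delta-beta attenuation
    test, FDR control and mechanism classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    tools,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
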