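Package: burdenscan
Title: Weighted Burden and Carrier-Based Rare-Variant Association Testing
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-panel rare-variant association analysis for heavily
    imbalanced case/control cohorts: composite phenotype definition from
    self-report, ICD-10 codes and medication use; per-subject weighted
    burden scores combining consequence-severity and minor-allele-frequency
    weights; covariate-adjusted logistic regression summarised as signed
    log10 p-values (SLP); variant-category regression with a Fisher exact
    fallback for sparse categories; single-variant and pooled carrier
    contingency tests; and a fully synthetic cohort generator (genotypes,
    annotations, covariates and phenotype indicators) so the whole pipeline
    is testable without restricted-access biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
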