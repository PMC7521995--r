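Package: carrierprs
Title: Polygenic Risk Score Modification of Cancer Penetrance in BRCA1/2
    Carriers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how polygenic risk scores (PRS) modify
    breast and epithelial ovarian cancer risks for carriers of BRCA1/BRCA2
    pathogenic variants.  Implements PRS construction from SNP weight
    tables and genotype dosages, outcome-specific censoring of carrier
    cohorts, calibration of age- and disease-specific sampling weights
    against external carrier incidence (correcting clinic-based
    ascertainment), stratified weighted Cox regression with
    family-clustered robust variance (continuous, categorical-percentile,
    age-varying and interaction models), Harrell's C with cluster
    bootstrap, left-truncated prospective validation, and a constrained
    baseline-hazard solver that converts per-SD hazard ratios plus an
    average carrier incidence curve into absolute (penetrance) risks by
    PRS percentile.  A synthetic-cohort generator with family-correlated
    PRS, ascertained sampling and competing censoring supports end-to-end
    testing and parameter-recovery studies without access to consortium
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml,
    jsonlite
Config/testthat/edition: 3
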