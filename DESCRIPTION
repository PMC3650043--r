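Package: recurrisk
Title: Risk Equations and Microsimulation for First and Second
    Cardiovascular Events in Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements Weibull proportional-hazards risk equations for
    first and second acute myocardial infarction, heart failure,
    non-acute ischaemic heart disease and stroke in type 2 diabetes,
    following the Prentice-Williams-Peterson gap-time formulation
    (separate equations and time scales by event order). Provides a
    published-equation library with linear splines, covariate and
    covariate-by-time interactions and mean-centred continuous
    covariates; interval risks, hazards and cumulative-hazard curves; a
    synthetic baseline-cohort generator; a patient-level microsimulator
    producing counting-process data; maximum-likelihood fitting of
    Weibull proportional-hazards models with delayed entry and
    time-varying covariates; and validation via Harrell's C and a
    modified Hosmer-Lemeshow calibration test with martingale-residual
    expected counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
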