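Package: mqtlmr
Title: Mendelian Randomization of DNA Methylation on Disease Risk with
    mQTL Instruments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to appraise whether blood DNA-methylation differences
    cause disease: conditional logistic regression for matched case-control
    epigenome-wide association studies (EWAS), inverse-variance-weighted
    fixed-effects meta-analysis with heterogeneity diagnostics, construction
    and vetting of methylation quantitative trait locus (mQTL) genetic
    instruments, one- and two-sample Mendelian randomization (Wald ratio,
    IVW, MR-Egger, correlated-instrument IVW, two-stage Cox regression) with
    sensitivity analyses and a-priori power, and a synthetic-data generator
    that reproduces the statistical structure of a smoking-confounded
    methylation-cancer study so that every stage is testable without access
    to consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    VariantAnnotation
Config/testthat/edition: 3
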