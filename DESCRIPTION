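Package: pedss
Title: Claims-Based Proxy Expanded Disability Status Scale for Multiple Sclerosis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a proxy Expanded Disability Status Scale (pEDSS) step
    (0-9) for people with multiple sclerosis from German administrative
    claims: ICD-10-GM diagnoses, ATC prescriptions and Hilfsmittel medical-aid
    codes observed in a window around an index date are mapped through a
    configurable symptom catalog and a deterministic rule cascade. Includes
    the rescaling of clinician-recorded EDSS measurements onto the 10-step
    proxy scale, eight-fold/three-fold/binary classifier groupings, a full
    one-vs-rest evaluation stack (sensitivity, specificity, PPV, NPV,
    accuracy, Cohen's kappa, F1, macro F1, MSE/MAE), a cohort-selection
    routine with attrition reporting, and a seeded synthetic-claims
    generator for testing the whole pipeline without access to real claims.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    caret,
    jsonlite,
    withr
Config/testthat/edition: 3
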