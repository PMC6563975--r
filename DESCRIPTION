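Package: ordival
Title: Ordinal Validation of Clinical Prediction Models for Childhood Pneumonia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Validation machinery for clinical prediction models of bacterial
    versus viral respiratory infection in children at the emergency department.
    Implements a five-category ordinal clinical reference standard (definite or
    probable bacterial through definite or probable viral) built from the working
    diagnosis, pathogen detection and C-reactive protein; declarative evaluation
    of rule-based and logistic prediction models; the ordinal c-statistic (ORC)
    with multiple-imputation pooling; threshold-based harm/benefit analysis of
    antibiotic-prescription policies; and a synthetic emergency-department
    cohort generator for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
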