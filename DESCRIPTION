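Package: registrylink
Title: Privacy-Preserving Deterministic Linkage of Health Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for patient-level linkage of health-care registries that
    lack a shared unique identifier. Implements a three-party pseudonymization
    chain (sender, trusted third party, receiver) over the quasi-identifier
    pair (date of birth, 4-digit postal code), a deterministic linkage
    algorithm with diagnosis-based disambiguation of non-unique keys,
    linkage-flow accounting, inclusion-bias tables with chi-square homogeneity
    tests, a general-practice validation-sample builder, collision and
    linkage-performance analytics, and a synthetic two-registry generator with
    ground truth for measuring linkage quality end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    openssl,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
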