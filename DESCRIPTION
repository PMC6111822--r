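Package: sigrev
Title: Prognostic Gene Signatures and Drug Signature-Reversal Screening by
    Connectivity Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for prognostic stratification of a driver gene in
    expression cohorts with right-censored survival data (median split,
    Kaplan-Meier restricted-mean survival, log-rank comparison), derivation
    of a cross-cohort co-regulated gene signature, and screening of that
    signature against a library of drug reference expression profiles using
    a signed-rank connection score with analytic, Monte-Carlo and exact
    permutation nulls, a leave-one-out signature perturbation stability
    test, and expected-false-positive significance control at one expected
    false discovery. Includes a synthetic-data generator for cohorts and
    reference libraries with planted signature-reversing drugs, readers and
    writers for the tabular formats involved, and an end-to-end pipeline
    driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
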