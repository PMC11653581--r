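Package: tdfent
Title: Transdermal Fentanyl Pharmacokinetics and Titration-Period Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two-arm analysis of transdermal fentanyl: a
    pharmacokinetic arm (model-independent moment analysis of
    concentration-time profiles, flip-flop one-compartment absorption-rate
    fitting, and decomposition of transdermal bioavailability into patch
    release and skin availability, F = Fa x Fskin) and a clinical arm
    (rule-based extraction of the dose-titration period from longitudinal
    medication records, followed by a univariate logistic screen and a
    multivariate adjusted-odds-ratio model). Includes synthetic-data
    generators for virtual-rat profiles with patch residuals and for
    patient cohorts with daily dose and rescue records, so the whole
    pipeline is testable end to end without access to raw animal or
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
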