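Package: callrhythm
Title: Rhythm, Tempo and Pulse-Pant Coupling Analysis of Primate Long Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the vocal rhythm of great-ape long calls
    annotated as event tables of voiced exhales (pulses) and voiced inhales
    (pants). Builds inter-onset interval series at four levels of temporal
    organization, computes interval ratios and classifies them into
    on-integer and off-integer rhythmic-category bins (isochrony 1:1,
    double meter 1:2 and 2:1), tests rhythmic categories with a
    zero-inflated Poisson mixed count model fitted by adaptive
    Gauss-Hermite quadrature, contrasts tempi across series types with a
    log-interval linear mixed model, and quantifies pulse-pant synchrony
    and directionality with lagged cross-correlation and order-1 Granger
    causality. Includes a synthetic long-call corpus generator with ground
    truth emulating tempo-variation and midpoint-inhale double-meter
    mechanisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    lme4,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    emmeans,
    lmtest,
    lmerTest,
    withr
Config/testthat/edition: 3
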