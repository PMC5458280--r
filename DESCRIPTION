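Package: pvsignal
Title: Disproportionality Signal Detection and Meta-Analysis for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection from spontaneous
    adverse-event report streams: cohort selection by drug indication,
    yearly 2x2 exposure-by-event contingency tables, reporting odds ratios
    (ROR) with Woolf confidence intervals, Cochran's Q / I-squared
    heterogeneity diagnostics, DerSimonian-Laird random-effects and
    Mantel-Haenszel fixed-effects pooling with leave-one-out sensitivity
    analysis, funnel-plot coordinates and Egger's regression test for
    reporting bias, and hypergeometric over-representation analysis of
    drug-interacting gene sets with Benjamini-Hochberg adjustment. A
    seeded synthetic report generator stands in for the FDA Adverse Event
    Reporting System so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
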