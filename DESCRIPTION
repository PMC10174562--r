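Package: reefresp
Title: Swimming Respirometry and Hypoxia Tolerance Analysis for Larval Reef Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stepped-velocity swimming respirometry and
    closed-chamber hypoxia trials on larval coral reef fish. Parses 1 Hz
    oxygen-logger traces, fits per-step oxygen depletion slopes with
    background (microbial) correction, computes mass-specific oxygen uptake
    rates, critical swimming speed (Ucrit), standard and maximum metabolic
    rates, absolute and factorial aerobic scope, and allometric mass-scaling
    exponents. Includes seawater gas-unit conversions between percent air
    saturation, oxygen partial pressure, and dissolved oxygen concentration;
    categorical-age group comparisons with Tukey-adjusted pairwise contrasts
    and compact letter displays; and a seeded synthetic-cohort generator that
    emulates larval growth, metabolic allometry, fatigue, sensor noise, and
    loss-of-equilibrium thresholds so every pipeline stage is testable
    without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
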