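Package: reefshift
Title: Thermal-Stress Climatology and Benthic Phase-Shift Analysis for
    Coral Reef Monitoring
Version: 0.1.0
Authors@R:
    person("Reef", "Monitoring", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying an El Nino-driven coral-to-algae phase
    shift from reef-monitoring data: a sea-surface-temperature climatology
    (maximum of monthly means, bleaching and cooling thresholds, a modified
    degree-heating-weeks series, annual threshold-exceedance trends), a
    from-scratch SIMPER decomposition of Bray-Curtis dissimilarity with
    permutation inference, Shannon diversity and bleaching-prevalence
    summaries from belt transects, and an Ecological Recovery Feasibility
    Index (ERFI) that ranks sites by natural-recovery potential using
    PCA-loading weights and expert direction weights. A synthetic-data
    generator reproduces the statistical structure of the field data so the
    whole pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
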