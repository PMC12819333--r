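Package: pvsignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of FAERS-style spontaneous
    adverse-event report databases: reading quarterly "$"-delimited ASCII
    tables, FDA-rule deduplication (latest FDA_DT per CASEID, PRIMARYID
    tiebreak), drug-name dictionary mapping and cohort construction,
    whole-database 2x2 disproportionality statistics (reporting odds ratio,
    proportional reporting ratio with chi-squared, Bayesian confidence
    propagation neural network information component, and multi-item gamma
    Poisson shrinker empirical-Bayes geometric mean) with standard positivity
    criteria, and time-to-onset characterization (Weibull shape-parameter
    hazard typing with bootstrap intervals, Kaplan-Meier cumulative onset,
    Mann-Whitney tests with Bonferroni adjustment). Includes a synthetic
    FAERS-format data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
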