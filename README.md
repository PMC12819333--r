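# pvsignal

Pharmacovigilance signal detection and time-to-onset analysis for
FAERS-style spontaneous adverse-event report databases.

Spontaneous reporting systems such as the FDA Adverse Event Reporting
System (FAERS) have no denominator, so drug risk cannot be estimated
directly; what can be measured is whether a drug–event pair is reported
*disproportionately* often. `pvsignal` implements the complete workflow
used in pharmacovigilance studies of immune-checkpoint-inhibitor (ICI)
associated bullous pemphigoid, and generalizes to any drug family and
event set via plain-text dictionaries and term lists:

- **Ingestion**: reading quarterly `"$"`-delimited ASCII tables (DEMO,
  DRUG, REAC, THER, OUTC, INDI; legacy `ISR`/`CASE` headers supported)
  and FDA-rule deduplication — per `CASEID`, keep the latest `FDA_DT`,
  ties broken by the highest `PRIMARYID`.
- **Cohort construction**: drug-name normalization and dictionary mapping
  (generic + brand synonyms), event selection by preferred-term list (a
  packaged pemphigoid list stands in for the licensed MedDRA SMQ), regimen
  classification (ICI monotherapy vs combination, primary-suspect role
  required), and Table-1-style demographic summaries.
- **Disproportionality**, on the report-level 2×2 table
  (a, b, c, d; N = a+b+c+d) against the whole remaining database:
  - reporting odds ratio `ROR = ad/bc` with Woolf 95% interval
    `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))` (Haldane 0.5 correction on
    zero cells);
  - proportional reporting ratio `PRR = [a/(a+b)]/[c/(c+d)]` with the 2×2
    Pearson χ²;
  - BCPNN information component `IC = log2 P(drug,event)/P(drug)P(event)`
    in the standard closed-form Bayesian shrinkage, with `IC025`;
  - MGPS empirical-Bayes geometric mean: negative-binomial-mixture
    marginal likelihood fit of the gamma-mixture prior over the full
    drug×event grid, posterior `EBGM` via digamma, `EBGM05` by bisection
    on the posterior CDF;
  - the usual positivity criteria (ROR > 1 with lower bound > 1 and
    a ≥ 3; PRR ≥ 2 with χ² ≥ 4 and a ≥ 3; IC025 > 0; EBGM05 > 2).
- **Time-to-onset**: validity filtering on partial dates, type-7 quartile
  summaries, Weibull shape-parameter hazard typing (β < 1 early failure /
  β ≈ 1 random / β > 1 wear-out, decided by seeded bootstrap percentile
  intervals), Kaplan–Meier cumulative onset, and pairwise Mann–Whitney
  tests with Bonferroni adjustment.
- **Synthetic data**: `synthetic_config()` / `generate_faers()` emit
  FAERS-format quarters with planted reporting-rate ratios, class-specific
  Weibull onset distributions, demographic marginals, partial-date
  degradation and duplicate case versions, plus closed-form expected cell
  counts (`expected_cells()`) as ground truth.

See `vignettes/pvsignal-methods.Rmd` for the models, assumptions, and
numerical choices.

## Worked example

Generate a synthetic database under the default study conditions (the
published ICI–pemphigoid cohort's marginals), run it through the pipeline,
and read the signal table:

```r
library(pvsignal)

cfg   <- synthetic_config(n_reports = 50000, seed = 42)
dir   <- file.path(tempdir(), "q1")
generate_faers(cfg, dir = dir)
store <- build_report_store(read_quarter(dir))
store
#> faers_store: 50000 deduplicated reports (52542 raw DEMO rows, 2542 duplicates dropped)

signal_table(store, list("all", "PD-1i", "nivolumab"))
#>    exposure  n   ROR ROR_low ROR_high   PRR  chi2 EBGM05 IC025 ror_pos bcpnn_pos
#> 1       all 58 19.63   13.42    28.71 19.25 465.5  11.37 2.576    TRUE      TRUE
#> 2     PD-1i 51 22.40   15.31    32.78 21.85 536.7  11.37 2.817    TRUE      TRUE
#> 3 nivolumab 31 15.87   10.42    24.18 15.51 300.7  11.37 2.516    TRUE      TRUE
```

Each row is one exposure: `n` is the number of deduplicated case reports
with both the exposure and a pemphigoid term; the four statistics agree
that reporting is 15–30× more frequent than expected under independence,
and every positivity flag fires (the generator planted a class-level rate
ratio of 22.7 for PD-1 inhibitors, so this is the expected recovery).

Onset characterization for the case cohort:

```r
reg <- classify_regimens(store$drug)
ev  <- select_event_reports(store$reac, default_pemphigoid_terms())
coh <- intersect(as.character(reg$primaryid[reg$regimen != "none"]), ev)
tto <- extract_tto(store, coh, reg)
fit_weibull(tto$tto_days[tto$status == "valid"], boot = 1000, seed = 7)
#> Weibull fit (n = 25): alpha = 236.30 (141.19, 342.26) days; beta = 0.948 (0.717, 1.432); random failure
```

With only 25 date-valid onsets the shape interval straddles 1, so the
hazard type is honestly reported as `random`; at the cohort sizes the
method targets (hundreds of valid onsets) the planted β = 0.83 class is
recovered as `early` (see the test suite).

`run_pipeline(run_config(...))` orchestrates the whole flow from quarter
directories to a report bundle (`signals.tsv`, `cohort_summary.tsv`,
`tto_tests.tsv`, `weibull.tsv`, `onset_curves.tsv`, `flow_counts.json`).
A thin command-line wrapper lives at `inst/scripts/pvsignal`.

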