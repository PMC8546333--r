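# pvdispro

Disproportionality signal detection for spontaneous adverse-event reports.

Spontaneous reporting systems such as the FDA Adverse Event Reporting
System (FAERS) collect voluntary reports of suspected adverse drug events.
Because report counts reflect reporting rather than incidence, safety
signals are generated by *disproportionality analysis*: a drug–event pair
is compared against the background of all other reports and flagged when it
is reported unexpectedly often. pvdispro is an R package for
pharmacovigilance analysts and pharmacoepidemiologists that implements this
workflow end to end:

* **I/O** — read/write the FAERS-style quarterly `$`-delimited ASCII tables
  (DEMO, DRUG, REAC, OUTC, THER, INDI), including the legacy ISR/CASE
  dialect, with exact round-trips.
* **Case pipeline** — deduplicate report versions per case identifier
  (latest `FDA_DT` wins), map verbatim drug names to a brand/generic
  synonym dictionary, filter by drug role (suspects only) and indication,
  flag event preferred terms, classify outcomes into mutually exclusive
  severity classes, and normalize demographics.
* **Statistics** — for each drug against the full background, the 2×2 table
  (a, b, c, d) and four statistics with signal criteria:
  - ROR = ad/bc, CI = exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)); signal when
    the CI lower bound > 1 and N ≥ 2
  - PRR = [a/(a+c)] / [b/(b+d)] with Pearson χ²; signal when PRR ≥ 2,
    χ² ≥ 4, N ≥ 3
  - BCPNN IC = log₂[a·n / ((a+b)(a+c))] with lower bound IC025; signal
    when IC025 > 0
  - simplified MGPS EBGM = a·n / ((a+b)(a+c)) with one-sided EBGM05 =
    exp(ln EBGM − 1.64·√(1/a+1/b+1/c+1/d)); signal when EBGM05 > 2, N > 0
    (no gamma-Poisson shrinkage is fitted — see the vignette)
* **Reporting** — characteristics summary table, per-year trend grid,
  per-drug outcome proportions, and a one-call `run_pipeline()`.
* **Synthetic reporting system** — `generate_bundle()` simulates a FAERS-like
  database with configurable margins, injected drug–event association
  strengths, duplicate report versions and missingness, with closed-form
  `ground_truth()` — so the whole pipeline is testable with no download.

## Worked example

Simulate a reporting system of 20,000 cases in which adalimumab carries an
injected relative reporting ratio of 3 for "Cardiac failure", then screen
four biologic agents against a cardiotoxicity term list:

```r
library(pvdispro)

cfg     <- read_generator_config(system.file("extdata", "demo_config.yaml",  package = "pvdispro"))
casedef <- read_case_definition(system.file("extdata", "demo_casedef.yaml", package = "pvdispro"))

bundle <- generate_bundle(cfg)   # deterministic for cfg$seed = 42
cases  <- assemble_cases(bundle, casedef)          # full background, deduplicated
signals <- screen_pairs(cases, names(casedef$drug_dictionary))
```

The screen prints one row per drug (statistics abridged):

```
      drug_id  a   ror ror_lower ror_upper   prr     chi2      ic  ic025  ebgm ebgm05
1   abatacept  3 0.669     0.213      2.10 0.673  0.48234 -0.5656 -2.216 0.676  0.259
2  adalimumab 56 2.323     1.744      3.10 2.264 35.09736  1.0695  0.655 2.099  1.651
3 tocilizumab  3 0.970     0.308      3.06 0.971  0.00263 -0.0421 -1.698 0.971  0.372
4  etanercept 11 0.667     0.365      1.22 0.672  1.75729 -0.5561 -1.426 0.680  0.411
```

Only the drug with the injected association signals: adalimumab is flagged
by the ROR (CI lower bound 1.744 > 1), PRR (2.264 ≥ 2 with χ² 35.1 ≥ 4)
and BCPNN (IC025 0.655 > 0) criteria; its EBGM05 of 1.651 stays below the
stricter MGPS threshold of 2 because the association is diluted across the
three-term event definition. The three null drugs signal nowhere. The
observed ROR (2.32) sits below the injected ratio for the same reason — the
case definition pools "Cardiac failure" with two unassociated terms; a
single-term screen recovers ≈ 3 (see the recovery study in the vignette).

Behind the scenes, the adalimumab 2×2 table over the 20,000-report
background is

```
             drug other drugs
event          56         373
other events 1188       18383
```

Descriptive outputs follow the same case table:

```r
summarize_cases(assemble_cases(bundle, casedef, keep = "cases"))
trend_by_year(assemble_cases(bundle, casedef, keep = "cases"))
run_pipeline(bundle, casedef, "out/")   # writes signals/summary/trends/outcomes TSVs
```

A thin CLI wrapper for shell use ships at `inst/scripts/pv_dispro.R`.

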