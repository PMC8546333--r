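---
title: "Disproportionality signal detection for spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvdispro)
```

## The problem

Spontaneous reporting systems such as the FDA Adverse Event Reporting System
(FAERS) collect voluntary reports of suspected adverse drug events. Report
counts reflect reporting behaviour, not incidence, so the standard way to
generate pharmacovigilance hypotheses from them is *disproportionality
analysis*: compare how often a drug–event pair is reported against the
background of all other reports, and flag pairs reported unexpectedly often.
pvdispro implements this end to end for FAERS-style data: quarterly ASCII
ingestion, case/non-case construction, four disproportionality statistics
with signal criteria, and descriptive reporting — all exercisable on a
bundled synthetic reporting-system generator with known ground truth.

## The case/non-case model

Every analysis reduces to the classical 2×2 table for one drug–event pair:

|                     | drug of interest | all other drugs | total |
|---------------------|------------------|-----------------|-------|
| event of interest   | a                | b               | a+b   |
| all other events    | c                | d               | c+d   |
| total               | a+c              | b+d             | n     |

built over the **full deduplicated background**: `d` counts reports with
neither the drug nor the event, so the case table handed to
`build_contingency()` must span all reports, not only those mentioning a
target drug. "Cases" are reports carrying an event term of interest;
"exposure" is presence of the drug among suspect drugs (primary or
secondary suspect roles by default; concomitant and interacting drugs do
not qualify).

Four statistics are computed per pair, with N = a:

* **ROR** (reporting odds ratio): $\mathrm{ROR} = ad/bc$, with the Wald
  interval $\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$.
  Signal: CI lower bound > 1 and N ≥ 2.
* **PRR** with Pearson χ²: $\mathrm{PRR} = \frac{a/(a+c)}{b/(b+d)}$;
  χ² is the plain four-cell Pearson statistic from the margins (no Yates
  correction by default; available by flag). Signal: PRR ≥ 2, χ² ≥ 4,
  N ≥ 3.
* **BCPNN information component**:
  $\mathrm{IC} = \log_2 \frac{a\,n}{(a+b)(a+c)}$, the base-2 log of the
  observed-to-expected reporting ratio. Signal: IC025 > 0.
* **Simplified MGPS**: $\mathrm{EBGM} = \frac{a\,n}{(a+b)(a+c)}$ with
  $\mathrm{EBGM05} = \exp(\ln \mathrm{EBGM} - 1.64\sqrt{1/a+1/b+1/c+1/d})$.
  Signal: EBGM05 > 2 and N > 0.

In these simplified closed forms IC = log2(EBGM) identically; the identity
is enforced by tests. **No gamma-Poisson mixture is fitted**: the EBGM here
is the raw observed/expected ratio, not the shrunken empirical-Bayes
estimate a full MGPS implementation would give. Small-count EBGM values are
therefore *larger* than true MGPS estimates, and EBGM05 at small N is
anti-conservative relative to real MGPS. Comparisons are strict (`>`) or
inclusive (`≥`) exactly as conventionally printed; every threshold in
`signal_criteria()` is configurable.

### Numerical choices

* **Zero cells.** A zero cell makes the log-scale intervals undefined; the
  affected statistics come back `NA` and never signal. An optional
  Haldane–Anscombe correction (`correction = "haldane"`) adds 0.5 to all
  four cells when any is zero; it is off by default so the plain closed
  forms are what you get. `n_reports` always reports the uncorrected `a`.
* **IC025.** The default lower bound subtracts 1.96 standard errors on the
  log2 scale: $\mathrm{IC} - (1.96/\ln 2)\sqrt{1/a+1/b+1/c+1/d}$. A
  multiplicative form $\mathrm{IC}\cdot e^{-1.96\sqrt{\cdot}}$ is sometimes
  printed in the field; it is undefined for IC ≤ 0 (the log of a negative
  number) and is available as the opt-in `ic_mode = "paper"`, returning
  `NA` below independence.
* **Integer overflow.** Cell products in the χ² expecteds exceed 32-bit
  integers at database scale; cells are held as doubles.

## From raw tables to the analysis dataset

`read_quarter()` reads the six `$`-delimited quarterly tables (DEMO, DRUG,
REAC, OUTC, THER, INDI), auto-detecting the legacy dialect (ISR/CASE
identifier columns, used by older releases) by header inspection and
normalizing it onto `primaryid`/`caseid`. Malformed rows are dropped with a
message up to a configurable tolerance and fatal beyond it. All fields stay
character in the bundle so `write_quarter()`/`read_quarter()` is an exact
round trip (values containing the delimiter are quoted).

`assemble_cases()` composes the pipeline:

1. **Deduplication.** FAERS emits a new report version per follow-up, all
   sharing a case identifier. One record per `caseid` is kept: the latest
   receipt date (`FDA_DT`); receipt-date ties keep the greatest report
   identifier, since identifiers increase with resubmission. Partial dates
   (`YYYYMM`, `YYYY`) are accepted, flagged, and compared with missing
   components treated as earliest — never interpolated.
2. **Drug mapping.** Verbatim names are normalized (case-fold, strip
   punctuation, collapse whitespace, drop trailing dose/formulation tokens)
   and matched against a brand/generic synonym dictionary. Matching is
   exact term equality after normalization by default; a substring mode
   exists for sensitivity analysis. A synonym claimed by two drugs is a
   configuration error, raised at load time. Only records in allowed roles
   (default PS, SS) qualify.
3. **Indication filter.** A (report, drug) match survives only if an
   indication record for that drug sequence normalizes into the configured
   indication terms (default: rheumatoid arthritis). The filter is applied
   per drug record, not per report — a report can keep one drug and lose
   another. An empty term set disables it.
4. **Event flagging.** Reaction preferred terms are matched by exact
   normalized equality against the configured event-term list. Exact
   matching is deliberate: PT vocabularies are controlled, and substring
   matching over-captures ("cardiac failure" would swallow "cardiac
   failure congestive", a different PT). The term list ships as an editable
   text config because MedDRA itself is licensed.
5. **Outcome classification.** Outcome codes collapse to one mutually
   exclusive severity class, most serious first: death (DE), else
   disability (DS or CA), else other-serious (LT, HO, RI, OT), else none.
   This prevents double counting across classes.
6. **Demographics.** Ages convert to years (DEC×10, MON÷12, WK÷52.1429,
   DY÷365.25, HR÷8766) and band as <18, 18–44, 45–64, 65–74, 75–84, >85.
   The conventional printed bands leave age 85 uncovered; it is assigned
   upward, i.e. bands are [75, 85) and [85, ∞). Countries map to six
   continents through a bundled ~300-entry table (ISO-style codes plus
   common full names); unmapped strings are "unknown", never dropped.

The assembled table keeps **every** deduplicated report — the background is
what the 2×2 tables count. The case definition decides suspect-drug
membership and event flags, not row retention; `keep = "exposed"` /
`keep = "cases"` restrict rows for descriptive outputs only.

### Descriptive outputs

`summarize_cases()` reproduces the usual characteristics table (suspect
drug, region, reporter, sex, age band, outcomes) with percentages of the
grand total. Percentages round **half-up** to two decimals, computed in
exact integer arithmetic so 0.005 boundaries never fall to floating-point
representation; published tables mix truncation and rounding, so one
convention is fixed here and documented. Outcomes appear both as raw code
counts (a report can be hospitalized *and* life-threatening, so the section
may exceed the total — as published tables do) and as the mutually
exclusive classes (a partition). `trend_by_year()` zero-fills a complete
(drug, year) grid; `outcome_proportions()` gives per-drug class
percentages. Multi-drug reports count once per drug in the per-drug
section, so that section can exceed the grand total when suspect drugs
co-occur.

## The synthetic reporting system

`generate_bundle()` draws a reporting system with known ground truth so
every stage is testable without any database download:

* Per case, each target drug is carried as a suspect with its marginal
  probability; each event occurs with its background probability times the
  relative reporting ratio (RR) of any exposed associated drug, capped
  at 1. When several associated drugs co-occur their RRs multiply. This
  multiplicative mechanism is the simplest one whose population 2×2 cells
  are available in closed form (`ground_truth()`:
  `E[a] = n·p_drug·min(1, p_event·RR)`, the rest by subtraction — exact
  when at most one drug is associated with a given event).
* A configurable fraction of cases is emitted as two report versions
  sharing the case identifier, with the earlier version backdated and the
  later one carrying the larger report identifier — exactly the structure
  the dedup rule must resolve. Child rows are replicated per version.
* Missingness blanks demographic fields only; identifiers and receipt
  dates are structurally required and never blanked.
* Every report carries one non-target background suspect drug and, when no
  event fires, a filler reaction term, so non-exposed reports look like
  real reports rather than empty shells.
* One pseudo-random stream per bundle, fully determined by the config
  seed; the caller's RNG state is saved and restored.

What it does **not** emulate: co-prescription correlation between drugs,
time-varying reporting rates, masking/competition bias, duplicate cases
under *different* case identifiers, misspelled drug names, and real MedDRA
coding noise. Passing tests on this generator therefore validate the
pipeline's bookkeeping and the statistics' sampling behaviour, not
robustness to real-world FAERS dirt.

### A note on population ROR under this mechanism

Because the association multiplies the event *probability*, the population
odds ratio exceeds RR:
$\mathrm{ROR}_\infty = \mathrm{RR}\,(1-p_e)/(1-p_e \mathrm{RR})$ for event
background probability $p_e$, and the population observed/expected ratio is
$\mathrm{EBGM}_\infty = \mathrm{RR}/(1 + p_\mathrm{use}(\mathrm{RR}-1))$.
Recovery experiments must therefore balance $p_e$ (drift of the ROR above
RR) against cell sizes (sampling noise). The packaged recovery study —
injected RR = 3 against three null comparators, recovered within
[2.5, 3.5] and flagged by all four criteria across 20 seeded replicates —
uses n = 120,000 reports per replicate with p_use = 0.15 and
p_event = 0.025. These values come from a design-stage normal-approximation
power analysis: they put roughly 2.9 standard errors between the expected
estimate and both window edges (population ROR 3.16, ln-scale SE ≈ 0.035)
and the same margin on EBGM05 > 2, so the 20-replicate criterion is met
with high probability while remaining a genuine sampling experiment. At
n = 50,000 no choice of margins achieves more than ≈ 1.75σ on both
constraints simultaneously — the window and the unshrunken EBGM05
threshold pull in opposite directions — which is why the larger replicate
size was fixed in advance. The null-calibration study (100 drugs × 20
events, all RR = 1, n = 20,000) checks that the ROR criterion flags at
about its nominal one-sided 2.5% level; pairs share the background, so
they are approximately rather than exactly independent.

## Known limitations

* EBGM/EBGM05 are unshrunken simplified forms; do not compare their
  small-count values against true MGPS output.
* No stratified (age/sex/year) or Mantel–Haenszel disproportionality; the
  background is pooled.
* No multiple-testing control across screened pairs — standard practice in
  this field, but worth remembering when screening many drugs.
* Signals are hypotheses about *reporting*, not estimates of risk; nothing
  here adjusts for usage, confounding, or reporting bias.
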