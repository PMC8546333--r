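Package: pvdispro
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for FAERS-style spontaneous
    reporting data: reads and writes the quarterly '$'-delimited ASCII
    tables (DEMO, DRUG, REAC, OUTC, THER, INDI), deduplicates report
    versions by case identifier and receipt date, applies a configurable
    drug/event/indication case definition, classifies outcomes into
    mutually exclusive severity groups, and computes four
    disproportionality statistics on the 2x2 contingency table --
    reporting odds ratio (ROR), proportional reporting ratio (PRR) with
    Pearson chi-squared, the Bayesian confidence propagation neural
    network information component (IC), and the simplified multi-item
    gamma Poisson shrinker EBGM -- together with confidence bounds
    and the standard signal criteria. A synthetic reporting-system
    generator with known ground truth makes the whole pipeline testable
    without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
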