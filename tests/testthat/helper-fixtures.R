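# Shared fixtures and independent oracles.

# Brute-force evaluation of every statistic straight from the defining
# formulas, independent of the package implementation: explicit loops and
# elementary arithmetic only.
oracle_stats <- function(a, b, c, d) {
  n <- a + b + c + d
  obs <- c(a, b, c, d)
  row_tot <- c(a + b, a + b, c + d, c + d)
  col_tot <- c(a + c, b + d, a + c, b + d)
  chi2 <- 0
  for (i in 1:4) {
    e <- row_tot[i] * col_tot[i] / n
    chi2 <- chi2 + (obs[i] - e)^2 / e
  }
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- (a / c) / (b / d)                 # odds vs odds
  ebgm <- a / ((a + b) * (a + c) / n)      # observed over expected
  list(
    ror = ror,
    ror_lower = exp(log(ror) - 1.96 * se),
    ror_upper = exp(log(ror) + 1.96 * se),
    prr = (a / (a + c)) / (b / (b + d)),
    chi2 = chi2,
    ic = log2(ebgm),
    ic025 = log2(ebgm) - 1.96 * se / log(2),
    ebgm = ebgm,
    ebgm05 = exp(log(ebgm) - 1.64 * se)
  )
}

# minimal two-drug / two-event generator configuration
tiny_config <- function(n = 500, seed = 1,
                        p_use = c(0.3, 0.2), p_event = c(0.1, 0.05),
                        rr = NULL, duplicate_rate = 0, missing_rate = 0) {
  generator_config(
    n_reports = n,
    drugs = list(
      list(id = "drug_a", synonyms = c("Alphadrug", "drug a"), p_use = p_use[1]),
      list(id = "drug_b", synonyms = c("Betadrug", "drug b"), p_use = p_use[2])
    ),
    events = list(
      list(term = "Cardiac failure", p = p_event[1]),
      list(term = "Nausea", p = p_event[2])
    ),
    associations = rr,
    duplicate_rate = duplicate_rate,
    missing_rate = missing_rate,
    seed = seed
  )
}

tiny_casedef <- function(...) {
  case_definition(
    drug_dictionary = list(drug_a = c("Alphadrug", "drug a"),
                           drug_b = c("Betadrug", "drug b")),
    event_terms = "Cardiac failure",
    indication_terms = character(0),
    ...
  )
}

# hand-built DEMO table for deduplication tests
demo_row <- function(primaryid, caseid, fda_dt, sex = "F") {
  tibble::tibble(primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
                 event_dt = "", sex = sex, age = "60", age_cod = "YR",
                 reporter_country = "US", occp_cod = "MD")
}
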