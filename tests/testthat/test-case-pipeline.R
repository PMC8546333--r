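test_that("deduplication keeps the latest receipt date, breaking ties upward", {
  demo <- dplyr::bind_rows(
    demo_row("100", "X", "20190101"),
    demo_row("105", "X", "20200315"),
    demo_row("200", "Y", "20180601")
  )
  out <- deduplicate_reports(demo)
  expect_equal(nrow(out), 2)
  expect_identical(out$primaryid[out$caseid == "X"], "105")
  expect_identical(out$primaryid[out$caseid == "Y"], "200")

  # receipt-date tie: greatest report identifier wins
  tie <- dplyr::bind_rows(demo_row("100", "X", "20200315"),
                          demo_row("101", "X", "20200315"))
  expect_identical(deduplicate_reports(tie)$primaryid, "101")
  # brute-force check over the pair: max by (date, id)
  key <- order(tie$fda_dt, as.numeric(tie$primaryid))
  expect_identical(deduplicate_reports(tie)$primaryid,
                   tie$primaryid[key[length(key)]])

  # idempotence, size, and case-id conservation
  demo_many <- generate_bundle(tiny_config(n = 300, seed = 5,
                                           duplicate_rate = 0.3))$demo
  once <- deduplicate_reports(demo_many)
  expect_identical(deduplicate_reports(once), once)
  expect_equal(nrow(once), length(unique(demo_many$caseid)))
  expect_setequal(once$caseid, unique(demo_many$caseid))
  expect_equal(nrow(deduplicate_reports(demo_many[0, ])), 0)
})

test_that("drug-name normalization strips dose and formulation noise", {
  expect_identical(normalize_drug_name("HUMIRA 40 MG INJECTION"), "humira")
  expect_identical(normalize_drug_name("etanercept"), "etanercept")
  expect_identical(normalize_drug_name("  Enbrel.  "), "enbrel")
  expect_identical(normalize_drug_name("Orencia 125MG solution"), "orencia")
  expect_identical(normalize_drug_name("ACTEMRA  (tocilizumab)  TABLET"),
                   "actemra tocilizumab")
  # a bare trailing number is dose noise; an embedded one is not
  expect_identical(normalize_drug_name("Drug 500"), "drug")
  expect_identical(normalize_drug_name("B12 Vitamin"), "b12 vitamin")
})

test_that("drug mapping honours roles, synonyms and ambiguity checks", {
  cd <- case_definition(
    drug_dictionary = list(adalimumab = c("Humira", "adalimumab"),
                           etanercept = c("Enbrel", "etanercept")),
    event_terms = "Cardiac failure",
    indication_terms = character(0)
  )
  drug <- tibble::tibble(
    primaryid = c("1", "2", "3", "3"),
    drug_seq = c("1", "1", "1", "2"),
    role_cod = c("PS", "C", "PS", "SS"),
    drugname = c("Humira", "Enbrel", "HUMIRA 40 MG", "enbrel."),
    prod_ai = ""
  )
  m <- map_drugs(drug, cd)
  expect_identical(m[["1"]], "adalimumab")
  expect_null(m[["2"]])            # concomitant-only report maps to nothing
  expect_identical(m[["3"]], c("adalimumab", "etanercept"))

  expect_error(
    case_definition(drug_dictionary = list(a = "same", b = "Same"),
                    event_terms = "x"),
    "ambiguous"
  )
})

test_that("indication filter keeps only matching drug-sequence records", {
  cd <- case_definition(
    drug_dictionary = list(adalimumab = "Humira"),
    event_terms = "Cardiac failure",
    indication_terms = "Rheumatoid arthritis"
  )
  matches <- tibble::tibble(primaryid = c("1", "2"), drug_seq = c("1", "1"),
                            drug_id = "adalimumab")
  indi <- tibble::tibble(primaryid = c("1", "2"),
                         indi_drug_seq = c("1", "1"),
                         indi_pt = c("Rheumatoid arthritis", "Psoriasis"))
  out <- apply_indication_filter(matches, indi, cd)
  expect_identical(out$primaryid, "1")
  # disabled filter is the identity
  cd0 <- case_definition(drug_dictionary = list(adalimumab = "Humira"),
                         event_terms = "x", indication_terms = character(0))
  expect_identical(apply_indication_filter(matches, indi, cd0), matches)
})

test_that("event flagging is exact term-level matching by default", {
  cd <- tiny_casedef()
  reac <- tibble::tibble(
    primaryid = c("1", "2", "3", "3", "4"),
    pt = c("Cardiac failure", "Nausea", "Nausea", "cardiac failure",
           "Cardiac failure congestive")
  )
  expect_setequal(flag_events(reac, cd), c("1", "3"))
  # substring mode over-captures deliberately
  cd_sub <- case_definition(
    drug_dictionary = list(drug_a = "Alphadrug"),
    event_terms = "Cardiac failure", indication_terms = character(0),
    match_mode = "substring"
  )
  expect_setequal(flag_events(reac, cd_sub), c("1", "3", "4"))
})

test_that("outcome classification partitions all code sets, most serious first", {
  expect_identical(classify_outcome(c("DE", "HO")), "death")
  expect_identical(classify_outcome("DS"), "disability")
  expect_identical(classify_outcome(c("HO", "LT")), "other-serious")
  expect_identical(classify_outcome("CA"), "disability")
  expect_identical(classify_outcome(character(0)), "none")
  expect_error(classify_outcome("ZZ"), "unknown outcome")
  # every subset of the vocabulary lands in exactly one class
  codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
  for (i in 0:(2^7 - 1)) {
    subset <- codes[bitwAnd(i, 2^(0:6)) > 0]
    cls <- classify_outcome(subset)
    expect_true(cls %in% c("death", "disability", "other-serious", "none"))
    if ("DE" %in% subset) expect_identical(cls, "death")
  }
})

test_that("age conversion applies the unit factors", {
  expect_equal(age_to_years(6, "MON"), 0.5)
  expect_equal(age_to_years(70, "YR"), 70)
  expect_equal(age_to_years(7, "DEC"), 70)
  expect_equal(age_to_years(730.5, "DY"), 2)
  expect_true(is.na(age_to_years(5, "unknown")))
  expect_error(age_to_years(-1, "YR"), "non-negative")
})

test_that("country mapping covers the six regions and defaults to unknown", {
  expect_identical(country_to_region(c("US", "DE", "JP", "BR", "AU", "ZA")),
                   c("North America", "Europe", "Asia", "South America",
                     "Oceania", "Africa"))
  expect_identical(country_to_region("UNITED STATES"), "North America")
  expect_identical(country_to_region(c("", "XX")), c("unknown", "unknown"))
})

test_that("assemble_cases composes the pipeline on a hand-built fixture", {
  # 10 raw reports: 8 cases (2 are duplicate versions), of which
  # 3 match only in excluded roles and 1 has the wrong indication
  demo <- dplyr::bind_rows(
    demo_row("1", "A", "20190101"), demo_row("2", "A", "20200101"),
    demo_row("3", "B", "20180101"), demo_row("4", "B", "20190601"),
    demo_row("5", "C", "20190301"), demo_row("6", "D", "20190401"),
    demo_row("7", "E", "20190501"), demo_row("8", "F", "20190601"),
    demo_row("9", "G", "20190701"), demo_row("10", "H", "20190801")
  )
  drug <- tibble::tibble(
    primaryid = as.character(c(2, 4, 5, 6, 7, 8, 9, 10)),
    drug_seq = "1",
    role_cod = c("PS", "PS", "C", "C", "I", "PS", "PS", "PS"),
    drugname = "Humira", prod_ai = ""
  )
  indi <- tibble::tibble(
    primaryid = as.character(c(2, 4, 8, 9, 10)), indi_drug_seq = "1",
    indi_pt = c("Rheumatoid arthritis", "Rheumatoid arthritis",
                "Psoriasis", "Rheumatoid arthritis", "Rheumatoid arthritis")
  )
  reac <- tibble::tibble(primaryid = as.character(1:10),
                         pt = rep("Cardiac failure", 10))
  outc <- tibble::tibble(primaryid = c("2", "4", "9"),
                         outc_cod = c("DE", "HO", "DS"))
  b <- faers_bundle(demo = demo, drug = drug, reac = reac, outc = outc,
                    indi = indi)
  cd <- case_definition(drug_dictionary = list(adalimumab = "Humira"),
                        event_terms = "Cardiac failure",
                        indication_terms = "Rheumatoid arthritis")
  all_rows <- assemble_cases(b, cd, keep = "all")
  expect_equal(nrow(all_rows), 8)                      # dedup only
  expect_false(anyDuplicated(all_rows$report_id) > 0)
  # survivors of role + indication filters: reports 2, 4, 9, 10
  exposed <- assemble_cases(b, cd, keep = "exposed")
  expect_setequal(exposed$report_id, c("2", "4", "9", "10"))
  expect_identical(sort(unique(exposed$outcome_class)),
                   c("death", "disability", "none", "other-serious"))
  # filters only ever shrink the retained set
  cd_nofilter <- case_definition(
    drug_dictionary = list(adalimumab = "Humira"),
    event_terms = "Cardiac failure", indication_terms = character(0),
    allowed_roles = c("PS", "SS", "C", "I")
  )
  expect_gte(nrow(assemble_cases(b, cd_nofilter, keep = "exposed")),
             nrow(exposed))
})

test_that("assembled demographics normalize sex, age band, region, reporter", {
  b <- generate_bundle(tiny_config(n = 400, seed = 31, missing_rate = 0.2))
  cases <- assemble_cases(b, tiny_casedef())
  # table-level outcome classes agree with the per-report classifier
  expect_identical(cases$outcome_class, classify_outcome(cases$outcome_codes))
  expect_true(all(cases$sex %in% c("M", "F", "unknown")))
  expect_true(all(cases$age_band %in% c("<18", "18-44", "45-64", "65-74",
                                        "75-84", ">85", "unknown")))
  expect_true(all(cases$region %in% c("North America", "Europe", "Asia",
                                      "South America", "Oceania", "Africa",
                                      "unknown")))
  expect_true(all(cases$reporter_type %in%
                    c("health-professional",
                      "consumer/non-health-professional", "unknown")))
  expect_true(all(cases$age_years >= 0, na.rm = TRUE))
})
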