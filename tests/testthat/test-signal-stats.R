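test_that("contingency construction counts the four cells of the fixture", {
  cases <- tibble::tibble(
    report_id = as.character(1:8),
    suspect_drug_ids = list("x", "x", character(0), "x", "x", "x",
                            character(0), character(0)),
    has_target_event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  t <- build_contingency(cases, "x")
  expect_equal(c(t$a, t$b, t$c, t$d), c(2, 1, 3, 2))

  # degenerate corner: every report has drug and event
  allin <- tibble::tibble(report_id = as.character(1:5),
                          suspect_drug_ids = rep(list("x"), 5),
                          has_target_event = rep(TRUE, 5))
  t2 <- build_contingency(allin, "x")
  expect_equal(c(t2$a, t2$b, t2$c, t2$d), c(5, 0, 0, 0))

  # margins are conserved
  expect_equal(t$a + t$b, sum(cases$has_target_event))
  expect_equal(t$a + t$c,
               sum(vapply(cases$suspect_drug_ids, function(s) "x" %in% s,
                          logical(1))))
  expect_error(build_contingency(cases[0, ], "x"), "non-empty")
})

test_that("point estimates and intervals match hand-derived values", {
  bal <- contingency_table(10, 10, 10, 10)
  expect_equal(ror(bal)$ror, 1)
  r <- ror(bal)
  # exp(+/- 1.96 sqrt(0.4))
  expect_equal(r$ci_lower, exp(-1.96 * sqrt(0.4)), tolerance = 1e-12)
  expect_equal(r$ci_upper, exp(1.96 * sqrt(0.4)), tolerance = 1e-12)
  expect_equal(round(r$ci_lower, 3), 0.289)
  expect_equal(round(r$ci_upper, 3), 3.454)
  expect_equal(prr_chi2(bal)$prr, 1)
  expect_equal(prr_chi2(bal)$chi2, 0)
  expect_equal(bcpnn_ic(bal)$ic, 0)
  expect_equal(mgps_ebgm(bal)$ebgm, 1)

  skew <- contingency_table(20, 10, 10, 20)
  expect_equal(ror(skew)$ror, 4)             # (20*20)/(10*10)
  expect_equal(prr_chi2(skew)$prr, 2)        # (20/30)/(10/30)
  expect_equal(prr_chi2(skew)$chi2, 100 / 15, tolerance = 1e-12)
  expect_equal(bcpnn_ic(skew)$ic, log2(4 / 3), tolerance = 1e-12)
  expect_equal(mgps_ebgm(skew)$ebgm, 4 / 3, tolerance = 1e-12)
  expect_equal(mgps_ebgm(skew)$ebgm05,
               (4 / 3) * exp(-1.64 * sqrt(0.3)), tolerance = 1e-12)
})

test_that("statistics agree with brute-force oracle and stats::chisq.test", {
  set.seed(101)
  for (i in 1:200) {
    cells <- sample(1:500, 4, replace = TRUE)
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    o <- oracle_stats(cells[1], cells[2], cells[3], cells[4])
    expect_equal(ror(t)$ror, o$ror, tolerance = 1e-12)
    expect_equal(ror(t)$ci_lower, o$ror_lower, tolerance = 1e-12)
    expect_equal(prr_chi2(t)$prr, o$prr, tolerance = 1e-12)
    expect_equal(prr_chi2(t)$chi2, o$chi2, tolerance = 1e-12)
    expect_equal(bcpnn_ic(t)$ic, o$ic, tolerance = 1e-12)
    expect_equal(mgps_ebgm(t)$ebgm, o$ebgm, tolerance = 1e-12)
    expect_equal(mgps_ebgm(t)$ebgm05, o$ebgm05, tolerance = 1e-12)
    if (i <= 25) {
      m <- matrix(c(cells[1], cells[3], cells[2], cells[4]), 2)
      ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
      expect_equal(prr_chi2(t)$chi2, unname(ref$statistic), tolerance = 1e-9)
    }
  }
})

test_that("zero cells flag undefined instead of erroring; Haldane correction restores estimates", {
  t0 <- contingency_table(0, 10, 10, 10)
  expect_true(is.na(ror(t0)$ror))
  expect_true(is.na(bcpnn_ic(t0)$ic))
  expect_true(is.na(mgps_ebgm(t0)$ebgm))
  rh <- ror(t0, correction = "haldane")
  expect_equal(rh$ror, (0.5 * 10.5) / (10.5 * 10.5), tolerance = 1e-12)
  # undefined statistics never signal
  res <- disproportionality(t0)
  expect_false(res$ror_signal)
  expect_false(res$bcpnn_signal)
  expect_false(res$mgps_signal)
})

test_that("IC modes: normal-approximation default and paper-literal multiplicative", {
  t <- contingency_table(40, 20, 20, 40)
  se <- sqrt(1 / 40 + 1 / 20 + 1 / 20 + 1 / 40)
  b_norm <- bcpnn_ic(t)
  expect_equal(b_norm$ic025, b_norm$ic - 1.96 * se / log(2), tolerance = 1e-12)
  b_pap <- bcpnn_ic(t, ic_mode = "paper")
  expect_equal(b_pap$ic025, b_pap$ic * exp(-1.96 * se), tolerance = 1e-12)
  # paper-literal form undefined at IC <= 0
  t_neg <- contingency_table(10, 40, 40, 10)
  expect_true(bcpnn_ic(t_neg, ic_mode = "paper")$ic < 0 ||
                is.na(bcpnn_ic(t_neg, ic_mode = "paper")$ic))
  expect_true(is.na(bcpnn_ic(t_neg, ic_mode = "paper")$ic025))
})

test_that("signal criteria apply the printed thresholds with their strictness", {
  mk <- function(n, ror_lower = NA, prr = NA, chi2 = NA, ic025 = NA,
                 ebgm05 = NA) {
    tibble::tibble(n_reports = n, ror_lower = ror_lower, prr = prr,
                   chi2 = chi2, ic025 = ic025, ebgm05 = ebgm05)
  }
  expect_true(evaluate_criteria(mk(5, ror_lower = 1.2))$ror_signal)
  expect_false(evaluate_criteria(mk(1, ror_lower = 1.2))$ror_signal)  # N >= 2
  expect_false(evaluate_criteria(mk(5, ror_lower = 1.0))$ror_signal)  # strict >
  expect_false(evaluate_criteria(mk(10, prr = 2.5, chi2 = 3))$prr_signal)
  expect_true(evaluate_criteria(mk(10, prr = 2, chi2 = 4))$prr_signal) # >= both
  expect_false(evaluate_criteria(mk(2, prr = 2.5, chi2 = 9))$prr_signal) # N >= 3
  expect_true(evaluate_criteria(mk(1, ic025 = 0.01))$bcpnn_signal)
  expect_false(evaluate_criteria(mk(1, ic025 = 0))$bcpnn_signal)       # strict
  expect_false(evaluate_criteria(mk(5, ebgm05 = 2))$mgps_signal)       # strict
  expect_true(evaluate_criteria(mk(1, ebgm05 = 2.01))$mgps_signal)
  expect_false(evaluate_criteria(mk(0, ebgm05 = 3))$mgps_signal)       # N > 0
})

test_that("independence and monotonicity properties hold", {
  set.seed(77)
  for (i in 1:50) {
    # tables with a/b = c/d are exactly null
    k <- sample(2:6, 1)
    b <- sample(5:50, 1)
    d <- sample(5:50, 1)
    t <- contingency_table(k * b, b, k * d, d)
    expect_equal(ror(t)$ror, 1, tolerance = 1e-9)
    expect_equal(prr_chi2(t)$prr, 1, tolerance = 1e-9)
    expect_equal(prr_chi2(t)$chi2, 0, tolerance = 1e-9)
    expect_equal(bcpnn_ic(t)$ic, 0, tolerance = 1e-9)
    expect_equal(mgps_ebgm(t)$ebgm, 1, tolerance = 1e-9)
  }
  # holding b, c, d fixed, ROR and EBGM strictly increase in a
  rors <- vapply(1:30, function(a)
    ror(contingency_table(a, 20, 15, 40))$ror, numeric(1))
  ebgms <- vapply(1:30, function(a)
    mgps_ebgm(contingency_table(a, 20, 15, 40))$ebgm, numeric(1))
  expect_true(all(diff(rors) > 0))
  expect_true(all(diff(ebgms) > 0))
})

test_that("screening several drugs matches individually computed results", {
  cfg <- tiny_config(n = 2000, seed = 11,
                     rr = data.frame(drug_id = "drug_a",
                                     event = "Cardiac failure", rr = 4))
  cases <- assemble_cases(generate_bundle(cfg), tiny_casedef())
  s <- screen_pairs(cases, c("drug_a", "drug_b"))
  expect_equal(nrow(s), 2)
  one <- disproportionality(build_contingency(cases, "drug_a"))
  expect_equal(s$ror[s$drug_id == "drug_a"], one$ror)
  expect_equal(s$chi2[s$drug_id == "drug_a"], one$chi2)
  # same data twice gives identical rows
  s2 <- screen_pairs(cases, c("drug_a", "drug_a"))
  expect_identical(s2[1, -1], s2[2, -1])
})
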