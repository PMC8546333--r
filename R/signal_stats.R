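#' Build a 2x2 contingency table for one drug-event pair
#'
#' Cross-classifies a case-report table into the four cells of the classical
#' disproportionality table: reports mentioning the drug of interest as a
#' suspect drug versus all other reports, against reports carrying the event
#' of interest versus all other reports.
#'
#' @param cases A case-report table as returned by [assemble_cases()]. It must
#'   span the full reporting background (all drugs and all events), not just
#'   reports of the target drug: the `d` cell counts reports with neither the
#'   drug nor the event.
#' @param drug_id Identifier of the drug of interest; matched against the
#'   `suspect_drug_ids` list-column.
#' @param event_flag Name of the logical column flagging the event of
#'   interest (default `"has_target_event"`), or a logical vector of
#'   `nrow(cases)`.
#' @return A `contingency_table` object: a list with integer cells `a`
#'   (drug and event), `b` (other drugs, event), `c` (drug, other events),
#'   `d` (neither), summing to `nrow(cases)`.
#' @examples
#' cases <- tibble::tibble(
#'   report_id = as.character(1:8),
#'   suspect_drug_ids = list("x", "x", NULL, "x", "x", "x", NULL, NULL),
#'   has_target_event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
#' )
#' build_contingency(cases, "x")
#' @export
build_contingency <- function(cases, drug_id, event_flag = "has_target_event") {
  if (!is.data.frame(cases) || nrow(cases) == 0L) {
    stop("`cases` must be a non-empty case-report table", call. = FALSE)
  }
  sets <- cases$suspect_drug_ids
  row_of <- rep(seq_len(nrow(cases)), lengths(sets))
  exposed <- logical(nrow(cases))
  exposed[row_of[unlist(sets, use.names = FALSE) == drug_id]] <- TRUE
  if (is.character(event_flag)) {
    event <- cases[[event_flag]]
  } else {
    event <- as.logical(event_flag)
  }
  stopifnot(length(event) == nrow(cases))
  contingency_table(
    a = sum(exposed & event),
    b = sum(!exposed & event),
    c = sum(exposed & !event),
    d = sum(!exposed & !event)
  )
}

#' Construct a contingency table from its four cells
#'
#' @param a,b,c,d Non-negative cell counts: `a` = drug of interest and event
#'   of interest, `b` = all other drugs with the event, `c` = drug of interest
#'   with all other events, `d` = neither.
#' @return A `contingency_table` object.
#' @export
contingency_table <- function(a, b, c, d) {
  # doubles: cell products in the chi-squared expecteds overflow 32-bit ints
  cells <- as.numeric(c(a = a, b = b, c = c, d = d))
  names(cells) <- c("a", "b", "c", "d")
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("contingency cells must be non-negative counts", call. = FALSE)
  }
  if (sum(cells) <= 0) {
    stop("contingency table must contain at least one report", call. = FALSE)
  }
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
              dimnames = list(c("event", "other events"),
                              c("drug", "other drugs")))
  cat("2x2 disproportionality table (n =", x$a + x$b + x$c + x$d, ")\n")
  print(m)
  invisible(x)
}

# Shared variance term of the log-scale Wald intervals: 1/a + 1/b + 1/c + 1/d.
.log_var <- function(t) 1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d

.apply_correction <- function(t, correction) {
  correction <- match.arg(correction, c("none", "haldane"))
  if (correction == "haldane" && min(t$a, t$b, t$c, t$d) == 0) {
    t <- contingency_table(t$a + 0.5, t$b + 0.5, t$c + 0.5, t$d + 0.5)
  }
  t
}

#' Reporting odds ratio with 95\% confidence interval
#'
#' ROR = (a d)/(b c); the two-sided interval is
#' exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' @param t A [contingency_table()].
#' @param correction Zero-cell handling: `"none"` (default; a zero cell
#'   yields `NA`, flagged not thrown) or `"haldane"` (+0.5 added to every
#'   cell when any cell is zero).
#' @return Named list with `ror`, `ci_lower`, `ci_upper` (all `NA` when
#'   undefined).
#' @examples
#' ror(contingency_table(20, 10, 10, 20))
#' @export
ror <- function(t, correction = c("none", "haldane")) {
  t <- .apply_correction(t, match.arg(correction))
  if (min(t$a, t$b, t$c, t$d) == 0) {
    return(list(ror = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_))
  }
  est <- (t$a * t$d) / (t$b * t$c)
  half <- 1.96 * sqrt(.log_var(t))
  list(ror = est,
       ci_lower = exp(log(est) - half),
       ci_upper = exp(log(est) + half))
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' PRR = \[a/(a+c)\] / \[b/(b+d)\]: the proportion of the event among the
#' drug's reports over its proportion among all other drugs' reports. The
#' chi-squared statistic is the plain Pearson sum over the four cells of
#' (O - E)^2 / E with expected counts from the margins; no Yates correction
#' by default.
#'
#' @inheritParams ror
#' @param yates Apply the Yates continuity correction to the chi-squared
#'   statistic (default `FALSE`).
#' @return Named list with `prr` and `chi2`; `NA` where a required margin is
#'   zero.
#' @examples
#' prr_chi2(contingency_table(20, 10, 10, 20))
#' @export
prr_chi2 <- function(t, correction = c("none", "haldane"), yates = FALSE) {
  t <- .apply_correction(t, match.arg(correction))
  n <- t$a + t$b + t$c + t$d
  prr <- if ((t$a + t$c) > 0 && (t$b + t$d) > 0 && t$b > 0) {
    (t$a / (t$a + t$c)) / (t$b / (t$b + t$d))
  } else {
    NA_real_
  }
  obs <- c(t$a, t$b, t$c, t$d)
  exp_ <- c((t$a + t$b) * (t$a + t$c), (t$a + t$b) * (t$b + t$d),
            (t$c + t$d) * (t$a + t$c), (t$c + t$d) * (t$b + t$d)) / n
  chi2 <- if (all(exp_ > 0)) {
    dev <- abs(obs - exp_)
    if (yates) dev <- pmax(dev - 0.5, 0)
    sum(dev^2 / exp_)
  } else {
    NA_real_
  }
  list(prr = prr, chi2 = chi2)
}

#' BCPNN information component with lower 95\% bound
#'
#' IC = log2\[a n / ((a+b)(a+c))\]: the base-2 log of the observed-to-expected
#' reporting ratio. The default lower bound subtracts 1.96 standard errors on
#' the log2 scale: IC025 = IC - (1.96/ln 2) sqrt(1/a + 1/b + 1/c + 1/d). The
#' `"paper"` mode instead computes the multiplicative form
#' IC exp(-1.96 sqrt(1/a + 1/b + 1/c + 1/d)), which is only defined for
#' IC > 0 and returns `NA` otherwise.
#'
#' @inheritParams ror
#' @param ic_mode `"normal"` (default) or `"paper"`; see Details.
#' @return Named list with `ic` and `ic025` (`NA` when undefined).
#' @examples
#' bcpnn_ic(contingency_table(20, 10, 10, 20))
#' @export
bcpnn_ic <- function(t, correction = c("none", "haldane"),
                     ic_mode = c("normal", "paper")) {
  ic_mode <- match.arg(ic_mode)
  t <- .apply_correction(t, match.arg(correction))
  if (min(t$a, t$b, t$c, t$d) == 0) {
    return(list(ic = NA_real_, ic025 = NA_real_))
  }
  n <- t$a + t$b + t$c + t$d
  ic <- log2(t$a * n / ((t$a + t$b) * (t$a + t$c)))
  sd_log <- sqrt(.log_var(t))
  ic025 <- if (ic_mode == "normal") {
    ic - (1.96 / log(2)) * sd_log
  } else if (ic > 0) {
    ic * exp(-1.96 * sd_log)
  } else {
    NA_real_
  }
  list(ic = ic, ic025 = ic025)
}

#' Simplified MGPS empirical Bayes geometric mean
#'
#' EBGM = a n / ((a+b)(a+c)), the raw observed-to-expected reporting ratio,
#' with the one-sided lower bound
#' EBGM05 = exp(ln EBGM - 1.64 sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' This is the simplified closed form only: no gamma-Poisson mixture is
#' fitted, so small-count values are NOT shrunk towards 1 and will exceed the
#' estimates of a full MGPS implementation. On this simplified form
#' IC = log2(EBGM) identically.
#'
#' @inheritParams ror
#' @return Named list with `ebgm` and `ebgm05` (`NA` when a cell is zero and
#'   no correction is applied).
#' @examples
#' mgps_ebgm(contingency_table(20, 10, 10, 20))
#' @export
mgps_ebgm <- function(t, correction = c("none", "haldane")) {
  t <- .apply_correction(t, match.arg(correction))
  if (min(t$a, t$b, t$c, t$d) == 0) {
    return(list(ebgm = NA_real_, ebgm05 = NA_real_))
  }
  n <- t$a + t$b + t$c + t$d
  ebgm <- t$a * n / ((t$a + t$b) * (t$a + t$c))
  list(ebgm = ebgm,
       ebgm05 = exp(log(ebgm) - 1.64 * sqrt(.log_var(t))))
}

#' Signal criteria thresholds
#'
#' The standard published criteria, each configurable:
#' \itemize{
#'   \item ROR: lower bound of the 95\% CI > 1 and N >= 2
#'   \item PRR: PRR >= 2 and chi-squared >= 4 and N >= 3
#'   \item BCPNN: IC025 > 0
#'   \item MGPS: EBGM05 > 2 and N > 0
#' }
#' N is the observed count `a`. Comparisons are strict (`>`) or inclusive
#' (`>=`) exactly as conventionally printed.
#'
#' @param ror_ci_lower,ror_min_n ROR thresholds.
#' @param prr_min,chi2_min,prr_min_n PRR thresholds.
#' @param ic025_min BCPNN threshold.
#' @param ebgm05_min,mgps_min_n MGPS thresholds.
#' @return A `signal_criteria` object.
#' @export
signal_criteria <- function(ror_ci_lower = 1, ror_min_n = 2,
                            prr_min = 2, chi2_min = 4, prr_min_n = 3,
                            ic025_min = 0,
                            ebgm05_min = 2, mgps_min_n = 0) {
  thresholds <- c(ror_ci_lower, ror_min_n, prr_min, chi2_min, prr_min_n,
                  ebgm05_min)
  if (any(thresholds <= 0)) {
    stop("signal criteria thresholds must be positive", call. = FALSE)
  }
  structure(list(ror_ci_lower = ror_ci_lower, ror_min_n = ror_min_n,
                 prr_min = prr_min, chi2_min = chi2_min, prr_min_n = prr_min_n,
                 ic025_min = ic025_min,
                 ebgm05_min = ebgm05_min, mgps_min_n = mgps_min_n),
            class = "signal_criteria")
}

#' Compute all disproportionality statistics for one table
#'
#' Evaluates ROR (with 95\% CI), PRR with Pearson chi-squared, the BCPNN
#' information component with its lower bound, and the simplified EBGM with
#' its one-sided lower bound, plus the four signal flags.
#'
#' @inheritParams ror
#' @inheritParams bcpnn_ic
#' @param criteria A [signal_criteria()] object.
#' @return A one-row tibble with columns `n_reports` (the observed `a` cell
#'   before any continuity correction), `ror`, `ror_lower`, `ror_upper`,
#'   `prr`, `chi2`, `ic`, `ic025`, `ebgm`, `ebgm05` and the logical flags
#'   `ror_signal`, `prr_signal`, `bcpnn_signal`, `mgps_signal`.
#' @examples
#' disproportionality(contingency_table(20, 10, 10, 20))
#' @export
disproportionality <- function(t, correction = c("none", "haldane"),
                               ic_mode = c("normal", "paper"),
                               criteria = signal_criteria()) {
  correction <- match.arg(correction)
  ic_mode <- match.arg(ic_mode)
  r <- ror(t, correction)
  p <- prr_chi2(t, correction)
  b <- bcpnn_ic(t, correction, ic_mode)
  m <- mgps_ebgm(t, correction)
  res <- tibble::tibble(
    n_reports = t$a,
    ror = r$ror, ror_lower = r$ci_lower, ror_upper = r$ci_upper,
    prr = p$prr, chi2 = p$chi2,
    ic = b$ic, ic025 = b$ic025,
    ebgm = m$ebgm, ebgm05 = m$ebgm05
  )
  evaluate_criteria(res, criteria)
}

#' Apply signal criteria to computed statistics
#'
#' Adds (or recomputes) the four per-algorithm signal flags. Undefined
#' statistics (`NA`) never flag.
#'
#' @param results A data frame with columns `n_reports`, `ror_lower`, `prr`,
#'   `chi2`, `ic025`, `ebgm05` (as produced by [disproportionality()] or
#'   [screen_pairs()]).
#' @param criteria A [signal_criteria()] object.
#' @return `results` with logical columns `ror_signal`, `prr_signal`,
#'   `bcpnn_signal`, `mgps_signal`.
#' @export
evaluate_criteria <- function(results, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  flag <- function(x) !is.na(x) & x
  n <- results$n_reports
  results$ror_signal <- flag(results$ror_lower > criteria$ror_ci_lower &
                               n >= criteria$ror_min_n)
  results$prr_signal <- flag(results$prr >= criteria$prr_min &
                               results$chi2 >= criteria$chi2_min &
                               n >= criteria$prr_min_n)
  results$bcpnn_signal <- flag(results$ic025 > criteria$ic025_min)
  results$mgps_signal <- flag(results$ebgm05 > criteria$ebgm05_min &
                                n > criteria$mgps_min_n)
  results
}

#' Screen several drugs against one event definition
#'
#' Builds the 2x2 table of each drug against the same full background and
#' computes all statistics and flags per drug.
#'
#' @inheritParams build_contingency
#' @inheritParams disproportionality
#' @param drug_ids Character vector of drug identifiers to screen.
#' @return A tibble with one row per drug: `drug_id`, the cell counts
#'   `a`, `b`, `c`, `d`, and all [disproportionality()] columns.
#' @export
screen_pairs <- function(cases, drug_ids, event_flag = "has_target_event",
                         correction = c("none", "haldane"),
                         ic_mode = c("normal", "paper"),
                         criteria = signal_criteria()) {
  if (length(drug_ids) < 1) stop("need at least one drug to screen", call. = FALSE)
  correction <- match.arg(correction)
  ic_mode <- match.arg(ic_mode)
  rows <- lapply(drug_ids, function(d) {
    t <- build_contingency(cases, d, event_flag)
    dplyr::bind_cols(
      tibble::tibble(drug_id = d, a = t$a, b = t$b, c = t$c, d = t$d),
      disproportionality(t, correction, ic_mode, criteria)
    )
  })
  dplyr::bind_rows(rows)
}
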