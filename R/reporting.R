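# Descriptive outputs: characteristics summary, yearly trend grid, outcome
# proportions, and the one-call pipeline driver.

#' Percentage of a count, rounded half-up to two decimals
#'
#' Computed in exact integer arithmetic (no floating-point representation of
#' the intermediate), so 0.005 boundaries always round up.
#'
#' @param count,total Non-negative counts, `total > 0`.
#' @return `round_half_up(100 * count / total, 2)`.
#' @examples
#' pct_of(2137, 3969)  # 53.84
#' @export
pct_of <- function(count, total) {
  stopifnot(all(total > 0))
  ((2e4 * count + total) %/% (2 * total)) / 100
}

.count_section <- function(values, levels, total, section) {
  cnt <- table(factor(values, levels = levels))
  tibble::tibble(section = section, label = levels,
                 count = as.integer(cnt[levels]),
                 percent = pct_of(as.integer(cnt[levels]), total))
}

#' Characteristics summary of a case-report table
#'
#' Produces the standard descriptive sections — suspect targeted therapy,
#' reporting region, reporter type, patient sex, patient age group, and
#' health outcomes — with counts and percentages of the grand total
#' (rounded half-up to two decimals).
#'
#' Outcomes appear twice, labeled distinctly: raw outcome-code counts (a
#' report hospitalized and life-threatening counts in both rows, so the
#' section need not sum to the total) and the mutually exclusive severity
#' classes (a partition).
#'
#' @param cases A case-report table from [assemble_cases()] — typically the
#'   `keep = "cases"` subset whose characteristics are being described.
#' @return A tibble with columns `section`, `label`, `count`, `percent`.
#' @export
summarize_cases <- function(cases) {
  if (nrow(cases) == 0) {
    stop("cannot summarize an empty case table", call. = FALSE)
  }
  total <- nrow(cases)
  drugs <- sort(unique(unlist(cases$suspect_drug_ids)))
  per_drug <- if (length(drugs) > 0) {
    cnt <- vapply(drugs, function(d)
      sum(vapply(cases$suspect_drug_ids, function(s) d %in% s, logical(1))),
      integer(1))
    tibble::tibble(section = "Targeted therapy as suspect drug",
                   label = drugs, count = as.integer(cnt),
                   percent = pct_of(as.integer(cnt), total))
  } else {
    NULL
  }
  code_labels <- c(DE = "Death", DS = "Disability", CA = "Congenital anomaly",
                   HO = "Hospitalization", LT = "Life-threatening",
                   RI = "Required intervention", OT = "Other serious")
  code_counts <- vapply(names(code_labels), function(k)
    sum(vapply(cases$outcome_codes, function(cd) k %in% cd, logical(1))),
    integer(1))
  dplyr::bind_rows(
    per_drug,
    .count_section(cases$region, c(.regions, "unknown"), total,
                   "Reporting region"),
    .count_section(cases$reporter_type,
                   c("health-professional", "consumer/non-health-professional",
                     "unknown"), total, "Reporters"),
    .count_section(ifelse(cases$sex == "M", "Male",
                          ifelse(cases$sex == "F", "Female", "unknown")),
                   c("Male", "Female", "unknown"), total, "Patient sex"),
    .count_section(cases$age_band, c(.age_bands, "unknown"), total,
                   "Patient age group (years)"),
    tibble::tibble(section = "Report-related health outcomes (codes)",
                   label = unname(code_labels),
                   count = as.integer(code_counts),
                   percent = pct_of(as.integer(code_counts), total)),
    .count_section(cases$outcome_class,
                   c("death", "disability", "other-serious", "none"), total,
                   "Health outcome class (mutually exclusive)")
  )
}

#' Reports per drug per receipt year
#'
#' A complete (drug, year) grid over the window, zero-filled: a year with no
#' reports is a zero row, never an absent row.
#'
#' @param cases A case-report table (typically the `keep = "cases"` subset).
#' @param years Integer vector of years defining the grid (default: the full
#'   span of receipt years present in `cases`).
#' @param drug_ids Drugs to tabulate (default: all drugs appearing in
#'   `suspect_drug_ids`).
#' @return A tibble `drug_id`, `year`, `n_reports`.
#' @export
trend_by_year <- function(cases, years = NULL, drug_ids = NULL) {
  if (is.null(years)) {
    rng <- range(cases$receipt_year, na.rm = TRUE)
    years <- seq(rng[1], rng[2])
  }
  if (is.null(drug_ids)) {
    drug_ids <- sort(unique(unlist(cases$suspect_drug_ids)))
  }
  long <- tidyr::unnest(
    cases[c("receipt_year", "suspect_drug_ids")],
    cols = "suspect_drug_ids"
  )
  long <- long[long$suspect_drug_ids %in% drug_ids, ]
  counts <- dplyr::count(long, .data$suspect_drug_ids, .data$receipt_year,
                         name = "n_reports")
  grid <- tidyr::expand_grid(drug_id = drug_ids, year = as.integer(years))
  out <- dplyr::left_join(
    grid, counts,
    by = c(drug_id = "suspect_drug_ids", year = "receipt_year")
  )
  out$n_reports[is.na(out$n_reports)] <- 0L
  out$n_reports <- as.integer(out$n_reports)
  out
}

#' Outcome-class proportions per drug
#'
#' For each drug, the percentage of its reports falling in each mutually
#' exclusive outcome class (death, disability, other-serious, none), of
#' that drug's case total; every class is present (0.00 when empty).
#'
#' @inheritParams trend_by_year
#' @return A tibble `drug_id`, `outcome_class`, `count`, `percent`.
#' @export
outcome_proportions <- function(cases, drug_ids = NULL) {
  if (is.null(drug_ids)) {
    drug_ids <- sort(unique(unlist(cases$suspect_drug_ids)))
  }
  classes <- c("death", "disability", "other-serious", "none")
  rows <- lapply(drug_ids, function(d) {
    sub <- cases[vapply(cases$suspect_drug_ids, function(s) d %in% s,
                        logical(1)), ]
    cnt <- table(factor(sub$outcome_class, levels = classes))
    tibble::tibble(drug_id = d, outcome_class = classes,
                   count = as.integer(cnt),
                   percent = if (nrow(sub) > 0)
                     pct_of(as.integer(cnt), nrow(sub)) else rep(0, 4))
  })
  dplyr::bind_rows(rows)
}

#' Run the full pipeline: ingest, cases, signals, summaries
#'
#' Reads (or accepts) a bundle and a case definition, assembles the
#' analysis dataset, screens every dictionary drug against the event
#' definition, and writes `signals.tsv`, `summary.tsv`, `trends.tsv`,
#' `outcomes.tsv` plus a `run_manifest.txt` recording inputs and the row
#' counts at every filter stage (screened, deduplicated, exposed, cases).
#'
#' @param bundle A [faers_bundle()] or a directory path for
#'   [read_quarter()].
#' @param case_def A [case_definition()] or a YAML path for
#'   [read_case_definition()].
#' @param out_dir Output directory (created if absent).
#' @param drug_ids Drugs to screen (default: every dictionary drug).
#' @inheritParams disproportionality
#' @return Invisibly, a list with the four output tibbles and the stage
#'   counts.
#' @export
run_pipeline <- function(bundle, case_def, out_dir,
                         drug_ids = NULL,
                         correction = c("none", "haldane"),
                         ic_mode = c("normal", "paper"),
                         criteria = signal_criteria()) {
  correction <- match.arg(correction)
  ic_mode <- match.arg(ic_mode)
  src_label <- function(x, what) {
    if (!is.character(x)) return(paste0("<in-memory ", what, ">"))
    files <- if (dir.exists(x)) list.files(x, full.names = TRUE) else x
    sums <- tryCatch(tools::md5sum(files), error = function(e) NULL)
    paste0(x, " [md5 ", paste(substr(unname(sums), 1, 8), collapse = " "),
           "]")
  }
  bundle_src <- src_label(bundle, "bundle")
  casedef_src <- src_label(case_def, "case definition")
  if (is.character(bundle)) bundle <- read_quarter(bundle)
  if (is.character(case_def)) case_def <- read_case_definition(case_def)
  if (is.null(drug_ids)) drug_ids <- names(case_def$drug_dictionary)

  background <- assemble_cases(bundle, case_def, keep = "all")
  exposed <- lengths(background$suspect_drug_ids) > 0
  case_rows <- background[exposed & background$has_target_event, ]
  counts <- c(
    screened = nrow(bundle$demo),
    deduplicated = nrow(background),
    exposed = sum(exposed),
    cases = nrow(case_rows)
  )

  signals <- screen_pairs(background, drug_ids,
                          correction = correction, ic_mode = ic_mode,
                          criteria = criteria)
  summary_tab <- summarize_cases(case_rows)
  trends <- trend_by_year(case_rows, drug_ids = drug_ids)
  outcomes <- outcome_proportions(case_rows, drug_ids = drug_ids)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_tsv <- function(x, name) {
    x <- as.data.frame(lapply(x, function(col)
      if (is.list(col)) vapply(col, paste, character(1), collapse = ";")
      else col), check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(signals, "signals.tsv")
  write_tsv(summary_tab, "summary.tsv")
  write_tsv(trends, "trends.tsv")
  write_tsv(outcomes, "outcomes.tsv")
  manifest <- c(
    "pvdispro run manifest",
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("bundle: ", bundle_src),
    paste0("case_definition: ", casedef_src),
    paste0("drugs screened: ", paste(drug_ids, collapse = ", ")),
    paste0("correction: ", correction, "   ic_mode: ", ic_mode),
    paste0("reports screened: ", counts["screened"]),
    paste0("reports after deduplication: ", counts["deduplicated"]),
    paste0("reports with a target suspect drug: ", counts["exposed"]),
    paste0("case reports (target drug + target event): ", counts["cases"])
  )
  writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  invisible(list(signals = signals, summary = summary_tab, trends = trends,
                 outcomes = outcomes, counts = counts))
}
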