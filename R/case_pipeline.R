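# From raw bundle to analysis dataset: dedup report versions, map verbatim
# drug names to dictionary ids, apply the case definition, classify outcomes.

#' Normalize a verbatim drug name
#'
#' Case-folds, trims, collapses internal whitespace, strips punctuation, and
#' removes trailing dose/formulation tokens (bare numbers, number+unit,
#' "tablet", "injection", "solution" and kin), so that
#' `"HUMIRA 40 MG INJECTION"` and `"Humira"` normalize identically.
#'
#' @param raw Character vector of verbatim names.
#' @return Normalized names.
#' @examples
#' normalize_drug_name("HUMIRA 40 MG INJECTION")
#' @export
normalize_drug_name <- function(raw) {
  x <- normalize_term(raw)
  units <- "mg|mcg|ug|g|kg|ml|l|iu|units?"
  form <- paste("tablets?|tab|injection|solution|capsules?|cap|cream",
                "ointment|syrup|suspension|pen|syringe|prefilled|kit|vial",
                "sc|subcutaneous|oral", sep = "|")
  # one trailing dose/formulation token; looped until none remain (the
  # leading space anchor guarantees at least one token survives)
  pat <- paste0(" ([0-9]+\\.?[0-9]*(", units, ")?|", units, "|", form, ")$")
  repeat {
    x2 <- sub(pat, "", x)
    if (identical(x2, x)) break
    x <- x2
  }
  x
}

#' Normalize a controlled-vocabulary term
#'
#' Case-folds, replaces punctuation with spaces, collapses whitespace and
#' trims. Used for reaction preferred terms and indication terms, where no
#' dose stripping applies.
#'
#' @param x Character vector.
#' @return Normalized terms.
#' @export
normalize_term <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[[:punct:]]+", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Define cases: drugs, events, roles, indications
#'
#' @param drug_dictionary Named list: `drug_id` -> character vector of
#'   brand/generic synonyms. Synonym sets must be disjoint across drugs
#'   after normalization (an ambiguous synonym is a configuration error).
#' @param event_terms Non-empty character vector of event preferred terms
#'   (a MedDRA PT surrogate list).
#' @param allowed_roles Drug role codes that qualify a report as exposed;
#'   default `c("PS", "SS")` — interacting and concomitant drugs excluded.
#' @param indication_terms Indication terms a matched drug record must carry
#'   to survive the indication filter; `character(0)` disables the filter.
#'   Default: rheumatoid arthritis.
#' @param match_mode `"exact"` (term-level equality after normalization;
#'   default) or `"substring"` (dictionary synonym contained in the
#'   normalized verbatim name; event term contained in the normalized PT).
#' @return A `case_definition` object.
#' @export
case_definition <- function(drug_dictionary,
                            event_terms,
                            allowed_roles = c("PS", "SS"),
                            indication_terms = "Rheumatoid arthritis",
                            match_mode = c("exact", "substring")) {
  match_mode <- match.arg(match_mode)
  if (length(event_terms) == 0) {
    stop("event_terms must be non-empty", call. = FALSE)
  }
  if (length(drug_dictionary) > 0 &&
      (is.null(names(drug_dictionary)) || any(!nzchar(names(drug_dictionary))))) {
    stop("drug_dictionary must be a named list of synonym vectors",
         call. = FALSE)
  }
  bad_roles <- setdiff(allowed_roles, .role_codes)
  if (length(bad_roles) > 0) {
    stop("unknown role code(s): ", paste(bad_roles, collapse = ", "),
         call. = FALSE)
  }
  syn_norm <- lapply(drug_dictionary, function(s) unique(normalize_drug_name(s)))
  all_syn <- unlist(syn_norm, use.names = FALSE)
  if (anyDuplicated(all_syn)) {
    dup <- unique(all_syn[duplicated(all_syn)])
    stop("ambiguous synonym(s) claimed by more than one drug: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(
    drug_dictionary = drug_dictionary,
    synonyms_normalized = syn_norm,
    event_terms = event_terms,
    event_terms_normalized = unique(normalize_term(event_terms)),
    allowed_roles = allowed_roles,
    indication_terms = indication_terms %||% character(0),
    indication_terms_normalized = unique(normalize_term(indication_terms %||%
                                                          character(0))),
    match_mode = match_mode
  ), class = "case_definition")
}

#' @export
print.case_definition <- function(x, ...) {
  cat("Case definition\n")
  cat(sprintf("  drugs: %d (%s matching)  roles: {%s}\n",
              length(x$drug_dictionary), x$match_mode,
              paste(x$allowed_roles, collapse = ", ")))
  cat(sprintf("  event terms: %d   indication filter: %s\n",
              length(x$event_terms),
              if (length(x$indication_terms) > 0) {
                paste0("on (", length(x$indication_terms), " terms)")
              } else "off"))
  invisible(x)
}

#' Read a case definition from a YAML file
#'
#' Keys: `drugs` (mapping drug_id -> synonym list), `events` (term list),
#' `allowed_roles`, `indication_terms`, `match_mode`.
#'
#' @param path YAML file path.
#' @return A [case_definition()].
#' @export
read_case_definition <- function(path) {
  y <- yaml::read_yaml(path)
  case_definition(
    drug_dictionary = lapply(y$drugs, unlist),
    event_terms = unlist(y$events),
    allowed_roles = unlist(y$allowed_roles) %||% c("PS", "SS"),
    indication_terms = if (is.null(y$indication_terms)) "Rheumatoid arthritis"
                       else unlist(y$indication_terms),
    match_mode = y$match_mode %||% "exact"
  )
}

#' Deduplicate report versions by case identifier
#'
#' FAERS emits a new report version per follow-up; versions share a case
#' identifier. Keeps exactly one record per `caseid`: the one with the
#' latest receipt date (`FDA_DT`), breaking receipt-date ties by the
#' greatest report identifier (numeric when all identifiers parse as
#' numbers, lexicographic otherwise — resubmissions get larger identifiers).
#' Partial receipt dates compare with missing components treated as
#' earliest. Idempotent; empty input returns empty output.
#'
#' @param demo A DEMO table (any columns; needs `primaryid`, `caseid`,
#'   `fda_dt`).
#' @return The subset of rows kept, one per distinct `caseid`, in order of
#'   first appearance of each case.
#' @export
deduplicate_reports <- function(demo) {
  if (nrow(demo) == 0) return(demo)
  d <- parse_faers_date(demo$fda_dt)$date
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  pid_key <- if (anyNA(pid_num)) demo$primaryid else pid_num
  ord <- order(demo$caseid, d, pid_key)
  keep <- ord[!duplicated(demo$caseid[ord], fromLast = TRUE)]
  demo[sort(keep), , drop = FALSE]
}

# internal: (primaryid, drug_seq, drug_id) rows for qualifying drug records
match_drug_records <- function(drug, case_def) {
  if (nrow(drug) == 0 || length(case_def$drug_dictionary) == 0) {
    return(tibble::tibble(primaryid = character(0), drug_seq = character(0),
                          drug_id = character(0)))
  }
  ok_role <- drug$role_cod %in% case_def$allowed_roles
  d <- drug[ok_role, c("primaryid", "drug_seq", "drugname")]
  d$norm <- normalize_drug_name(d$drugname)
  ids <- names(case_def$synonyms_normalized)
  if (case_def$match_mode == "exact") {
    lut <- stats::setNames(
      rep(ids, lengths(case_def$synonyms_normalized)),
      unlist(case_def$synonyms_normalized, use.names = FALSE)
    )
    d$drug_id <- unname(lut[d$norm])
    out <- d[!is.na(d$drug_id), c("primaryid", "drug_seq", "drug_id")]
  } else {
    hits <- lapply(ids, function(id) {
      pat <- case_def$synonyms_normalized[[id]]
      hit <- Reduce(`|`, lapply(pat, function(p) grepl(p, d$norm,
                                                       fixed = TRUE)))
      if (any(hit)) {
        tibble::tibble(primaryid = d$primaryid[hit],
                       drug_seq = d$drug_seq[hit], drug_id = id)
      }
    })
    out <- dplyr::bind_rows(hits)
    if (nrow(out) == 0) {
      out <- tibble::tibble(primaryid = character(0),
                            drug_seq = character(0), drug_id = character(0))
    }
  }
  dplyr::distinct(tibble::as_tibble(out))
}

#' Map reports to dictionary drugs
#'
#' A report maps to a drug iff it carries at least one drug record in an
#' allowed role whose normalized verbatim name matches one of the drug's
#' synonyms under the configured match mode. Reports whose only matches sit
#' in excluded roles (concomitant, interacting) map to nothing.
#'
#' @param drug A DRUG table.
#' @param case_def A [case_definition()].
#' @return Named list: `primaryid` -> character vector of matched drug ids
#'   (reports with no match are absent).
#' @export
map_drugs <- function(drug, case_def) {
  m <- match_drug_records(drug, case_def)
  lapply(split(m$drug_id, m$primaryid), function(x) sort(unique(x)))
}

#' Filter drug matches by indication
#'
#' A (report, drug) match survives iff some indication record for the
#' matching drug sequence normalizes into the configured indication terms.
#' An empty indication-term set disables the filter (identity).
#'
#' @param matches Tibble of matched records (`primaryid`, `drug_seq`,
#'   `drug_id`) as produced by the drug-mapping step.
#' @param indi An INDI table.
#' @param case_def A [case_definition()].
#' @return The filtered `matches` tibble.
#' @export
apply_indication_filter <- function(matches, indi, case_def) {
  if (length(case_def$indication_terms) == 0) return(matches)
  ok <- indi[normalize_term(indi$indi_pt) %in%
               case_def$indication_terms_normalized,
             c("primaryid", "indi_drug_seq")]
  keep <- paste(matches$primaryid, matches$drug_seq) %in%
    paste(ok$primaryid, ok$indi_drug_seq)
  matches[keep, , drop = FALSE]
}

#' Flag reports carrying an event of interest
#'
#' @param reac A REAC table.
#' @param case_def A [case_definition()]; matching is term-level equality of
#'   normalized terms (substring containment under
#'   `match_mode = "substring"`).
#' @return Character vector of `primaryid`s with at least one matching
#'   reaction term.
#' @export
flag_events <- function(reac, case_def) {
  if (nrow(reac) == 0) return(character(0))
  norm <- normalize_term(reac$pt)
  if (case_def$match_mode == "exact") {
    hit <- norm %in% case_def$event_terms_normalized
  } else {
    hit <- Reduce(`|`, lapply(case_def$event_terms_normalized,
                              function(p) grepl(p, norm, fixed = TRUE)))
  }
  unique(reac$primaryid[hit])
}

#' Classify outcome codes into one mutually exclusive severity class
#'
#' Most serious class wins, preventing double counting: death if `DE` is
#' present; else disability if `DS` or `CA` (congenital anomaly); else
#' other-serious if any of `LT`, `HO`, `RI`, `OT`; else none.
#'
#' @param codes Character vector of outcome codes for one report (possibly
#'   empty), or a list of such vectors.
#' @return A single class (`"death"`, `"disability"`, `"other-serious"`,
#'   `"none"`), or a character vector when `codes` is a list.
#' @examples
#' classify_outcome(c("DE", "HO"))
#' classify_outcome(c("HO", "LT"))
#' @export
classify_outcome <- function(codes) {
  if (is.list(codes)) {
    return(vapply(codes, classify_outcome, character(1)))
  }
  codes <- codes[nzchar(codes)]
  bad <- setdiff(codes, .outcome_codes)
  if (length(bad) > 0) {
    stop("unknown outcome code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if ("DE" %in% codes) return("death")
  if (any(c("DS", "CA") %in% codes)) return("disability")
  if (any(c("LT", "HO", "RI", "OT") %in% codes)) return("other-serious")
  "none"
}

#' Convert an age value with FAERS unit code to years
#'
#' Factors: `DEC` x10, `YR` x1, `MON` /12, `WK` /52.1429, `DY` /365.25,
#' `HR` /8766. Unknown units give `NA`.
#'
#' @param age_value Non-negative numeric vector.
#' @param age_unit Unit code vector, recycled against `age_value`.
#' @return Age in years (`NA` where value missing or unit unknown).
#' @examples
#' age_to_years(6, "MON")
#' age_to_years(7, "DEC")
#' @export
age_to_years <- function(age_value, age_unit) {
  age_value <- as.numeric(age_value)
  if (any(!is.na(age_value) & age_value < 0)) {
    stop("age_value must be non-negative", call. = FALSE)
  }
  factors <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1429,
               DY = 1 / 365.25, HR = 1 / 8766)
  f <- factors[toupper(as.character(age_unit))]
  unname(age_value * f)
}

.age_bands <- c("<18", "18-44", "45-64", "65-74", "75-84", ">85")

# [75,85) is "75-84", [85,Inf) is ">85" — the printed bands leave 85
# uncovered; it is assigned upward.
age_band <- function(years) {
  cut(years, breaks = c(-Inf, 18, 45, 65, 75, 85, Inf),
      labels = .age_bands, right = FALSE)
}

.regions <- c("North America", "Europe", "Asia", "South America",
              "Oceania", "Africa")

.region_env <- new.env(parent = emptyenv())

region_lookup <- function() {
  if (is.null(.region_env$map)) {
    path <- system.file("extdata", "country_regions.tsv",
                        package = "pvdispro", mustWork = TRUE)
    m <- utils::read.delim(path, sep = "\t", colClasses = "character")
    .region_env$map <- stats::setNames(m$region, toupper(m$country))
  }
  .region_env$map
}

#' Map a country code or name to its reporting region
#'
#' Uses the bundled country-to-continent table (ISO-style two-letter codes
#' plus common full names). Unmapped or empty strings map to `"unknown"`.
#'
#' @param country Character vector.
#' @return Region: one of North America, Europe, Asia, South America,
#'   Oceania, Africa, unknown.
#' @export
country_to_region <- function(country) {
  lut <- region_lookup()
  out <- unname(lut[toupper(trimws(as.character(country)))])
  out[is.na(out)] <- "unknown"
  out
}

.reporter_type <- function(occp_cod) {
  hp <- c("MD", "PH", "OT", "HP", "RN")
  cons <- c("CN", "LW")
  ifelse(occp_cod %in% hp, "health-professional",
         ifelse(occp_cod %in% cons, "consumer/non-health-professional",
                "unknown"))
}

#' Assemble the analysis dataset from a bundle
#'
#' Composes the pipeline: deduplicate report versions, map suspect drugs,
#' apply the indication filter, flag the events of interest, classify
#' outcomes, and normalize demographics (sex, age in years and band,
#' country to region, reporter type). The result keeps every deduplicated
#' report by default — the full background is what the 2x2 tables count;
#' the case-definition filters decide suspect-drug membership, not row
#' retention.
#'
#' @param bundle A [faers_bundle()].
#' @param case_def A [case_definition()], or `NULL` for a structure-only
#'   assembly (no drug/event matching).
#' @param keep Which rows to return: `"all"` (default, the full
#'   background), `"exposed"` (>= 1 matched suspect drug), or `"cases"`
#'   (exposed and carrying a target event).
#' @return A tibble with one row per retained deduplicated report:
#'   `report_id`, `case_id`, `suspect_drug_ids` (list-column),
#'   `has_target_event`, `outcome_codes` (list-column), `outcome_class`,
#'   `receipt_date`, `receipt_year`, `sex`, `age_years`, `age_band`,
#'   `region`, `reporter_type`.
#' @export
assemble_cases <- function(bundle, case_def = NULL,
                           keep = c("all", "exposed", "cases")) {
  keep <- match.arg(keep)
  validate_bundle(bundle)
  demo <- deduplicate_reports(bundle$demo)
  ids <- demo$primaryid

  if (!is.null(case_def)) {
    matches <- match_drug_records(bundle$drug, case_def)
    matches <- matches[matches$primaryid %in% ids, , drop = FALSE]
    matches <- apply_indication_filter(matches, bundle$indi, case_def)
    drug_sets <- lapply(split(matches$drug_id, matches$primaryid),
                        function(x) sort(unique(x)))
    event_ids <- flag_events(bundle$reac, case_def)
  } else {
    drug_sets <- list()
    event_ids <- character(0)
  }
  suspect <- drug_sets[ids]
  suspect[vapply(suspect, is.null, logical(1))] <- list(character(0))

  outc_sets <- split(bundle$outc$outc_cod, bundle$outc$primaryid)
  codes <- outc_sets[ids]
  codes[vapply(codes, is.null, logical(1))] <- list(character(0))
  # vectorized equivalent of classify_outcome() over the whole table
  oc <- bundle$outc
  cls <- rep("none", length(ids))
  cls[ids %in% oc$primaryid[oc$outc_cod %in% c("LT", "HO", "RI", "OT")]] <-
    "other-serious"
  cls[ids %in% oc$primaryid[oc$outc_cod %in% c("DS", "CA")]] <- "disability"
  cls[ids %in% oc$primaryid[oc$outc_cod == "DE"]] <- "death"

  receipt <- parse_faers_date(demo$fda_dt)$date
  age_years <- age_to_years(ifelse(demo$age == "", NA, demo$age),
                            ifelse(demo$age_cod == "", "unknown",
                                   demo$age_cod))
  out <- tibble::tibble(
    report_id = ids,
    case_id = demo$caseid,
    suspect_drug_ids = unname(suspect),
    has_target_event = ids %in% event_ids,
    outcome_codes = unname(codes),
    outcome_class = cls,
    receipt_date = receipt,
    receipt_year = as.integer(format(receipt, "%Y")),
    sex = ifelse(demo$sex %in% c("M", "F"), demo$sex, "unknown"),
    age_years = age_years,
    age_band = as.character(
      ifelse(is.na(age_years), "unknown", as.character(age_band(age_years)))),
    region = country_to_region(demo$reporter_country),
    reporter_type = .reporter_type(demo$occp_cod)
  )
  exposed <- lengths(out$suspect_drug_ids) > 0
  switch(keep,
         all = out,
         exposed = out[exposed, , drop = FALSE],
         cases = out[exposed & out$has_target_event, , drop = FALSE])
}
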