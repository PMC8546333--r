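# Synthetic spontaneous-reporting system with known ground truth.
#
# Each simulated case is one patient report: target-drug exposure is
# Bernoulli per drug, event occurrence is Bernoulli with the background
# probability multiplied by the relative reporting ratio (RR) of any exposed
# associated drug (capped at 1), so the population-level 2x2 cells — and
# hence the population ROR — are available in closed form. A configurable
# fraction of cases is emitted as two report versions sharing a case
# identifier, exercising the CASEID/FDA_DT deduplication rule downstream.

.default_outcome_probs <- c(DE = 0.10, LT = 0.05, HO = 0.40, DS = 0.02,
                            CA = 0.002, RI = 0.005, OT = 0.30)

.default_demographics <- list(
  sex = c(M = 0.35, F = 0.65),
  age_group = c("<18" = 0.02, "18-44" = 0.13, "45-64" = 0.40,
                "65-74" = 0.27, "75-84" = 0.14, ">85" = 0.04),
  country = c(US = 0.50, CA = 0.04, BR = 0.04, DE = 0.06, FR = 0.05,
              GB = 0.06, IT = 0.03, JP = 0.05, CN = 0.02, IN = 0.02,
              AU = 0.02, NZ = 0.005, ZA = 0.01, EG = 0.005, AR = 0.02,
              MX = 0.02, ES = 0.02, NL = 0.015, KR = 0.015),
  reporter = c("health-professional" = 0.55,
               "consumer" = 0.45)
)

# verbatim names for the non-target background drugs every report carries
.background_drugs <- paste0("BACKGROUND AGENT ", 1:20)
.background_pts <- c("Drug ineffective", "Nausea", "Headache", "Fatigue",
                     "Rash", "Dizziness", "Arthralgia", "Pyrexia")

.check_dist <- function(x, what) {
  if (length(x) == 0 || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(what, " must be a named probability vector", call. = FALSE)
  }
  if (any(x < 0 | x > 1)) {
    stop(what, " has probabilities outside [0,1]", call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    stop(what, " probabilities must sum to 1 (got ", format(sum(x)), ")",
         call. = FALSE)
  }
  x
}

#' Configure the synthetic reporting-system generator
#'
#' @param n_reports Number of cases (distinct patients/case identifiers).
#' @param drugs Target drugs: a list of `list(id =, synonyms =, p_use =)`
#'   entries, where `p_use` is the marginal probability that a case carries
#'   the drug as a suspect drug.
#' @param events Adverse-event vocabulary: a list of `list(term =, p =)`
#'   entries with background reporting probabilities.
#' @param associations Injected signals: a data frame (or list of lists)
#'   with columns `drug_id`, `event`, `rr` — the true relative reporting
#'   ratio (>= 0; 1 = no association; 0 = event never reported with the
#'   drug). Pairs not listed have RR 1.
#' @param duplicate_rate Fraction in `[0,1)` of cases emitted as two report
#'   versions sharing the case identifier.
#' @param missing_rate Fraction in `[0,1]` of demographic fields (sex, age,
#'   country, reporter) independently blanked; identifiers and receipt dates
#'   are never blanked.
#' @param date_range Inclusive receipt-date window, length-2 `Date` (or
#'   coercible) vector.
#' @param outcome_probs Named probabilities of each outcome code
#'   (DE, LT, HO, DS, CA, RI, OT), drawn independently per case; they need
#'   not sum to 1 (a report may carry several outcome codes, or none).
#' @param demographics List of named category distributions: `sex`,
#'   `age_group` (over the standard age bands), `country` (ISO-style codes),
#'   `reporter`; each must sum to 1 within 1e-9.
#' @param indications Named distribution of indication terms attached to
#'   target-drug records (default: all records indicate rheumatoid
#'   arthritis).
#' @param seed Integer seed; one pseudo-random stream per bundle, fully
#'   determined by it.
#' @return A validated `generator_config` object.
#' @export
generator_config <- function(n_reports,
                             drugs,
                             events,
                             associations = NULL,
                             duplicate_rate = 0,
                             missing_rate = 0,
                             date_range = as.Date(c("2004-01-01", "2020-09-30")),
                             outcome_probs = .default_outcome_probs,
                             demographics = .default_demographics,
                             indications = c("Rheumatoid arthritis" = 1),
                             seed = 1L) {
  if (!is.numeric(n_reports) || n_reports < 1) {
    stop("n_reports must be a positive count", call. = FALSE)
  }
  norm_entries <- function(x, id_field, p_field, what) {
    out <- lapply(x, function(e) {
      if (is.null(e[[id_field]]) || is.null(e[[p_field]])) {
        stop(what, " entries need `", id_field, "` and `", p_field, "`",
             call. = FALSE)
      }
      p <- as.numeric(e[[p_field]])
      if (is.na(p) || p < 0 || p > 1) {
        stop(what, " probability outside [0,1] for ", e[[id_field]],
             call. = FALSE)
      }
      e
    })
    out
  }
  drugs <- norm_entries(drugs, "id", "p_use", "drugs")
  events <- norm_entries(events, "term", "p", "events")
  drug_ids <- vapply(drugs, `[[`, character(1), "id")
  event_terms <- vapply(events, `[[`, character(1), "term")
  if (anyDuplicated(drug_ids)) stop("duplicate drug ids", call. = FALSE)
  if (anyDuplicated(event_terms)) stop("duplicate event terms", call. = FALSE)
  for (d in drugs) {
    if (is.null(d$synonyms) || length(d$synonyms) == 0) {
      stop("drug ", d$id, " has no synonyms", call. = FALSE)
    }
  }

  if (is.null(associations)) {
    associations <- data.frame(drug_id = character(0), event = character(0),
                               rr = numeric(0))
  } else if (!is.data.frame(associations)) {
    associations <- do.call(rbind, lapply(associations, function(a) {
      data.frame(drug_id = a$drug_id %||% a$drug, event = a$event,
                 rr = as.numeric(a$rr))
    }))
  }
  associations <- tibble::as_tibble(associations)
  bad_drug <- setdiff(associations$drug_id, drug_ids)
  bad_event <- setdiff(associations$event, event_terms)
  if (length(bad_drug) || length(bad_event)) {
    stop("association references undeclared ",
         paste(c(if (length(bad_drug)) paste("drug:", bad_drug),
                 if (length(bad_event)) paste("event:", bad_event)),
               collapse = "; "), call. = FALSE)
  }
  if (any(associations$rr < 0) || anyNA(associations$rr)) {
    stop("relative reporting ratios must be >= 0", call. = FALSE)
  }

  if (duplicate_rate < 0 || duplicate_rate >= 1) {
    stop("duplicate_rate must be in [0,1)", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must be in [0,1]", call. = FALSE)
  }
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || anyNA(date_range) ||
      date_range[2] < date_range[1]) {
    stop("date_range must be two ordered dates", call. = FALSE)
  }
  outcome_probs <- outcome_probs[.outcome_codes[.outcome_codes %in%
                                                  names(outcome_probs)]]
  if (any(outcome_probs < 0 | outcome_probs > 1)) {
    stop("outcome probabilities must lie in [0,1]", call. = FALSE)
  }
  for (nm in c("sex", "age_group", "country", "reporter")) {
    demographics[[nm]] <- .check_dist(demographics[[nm]],
                                      paste0("demographics$", nm))
  }
  indications <- .check_dist(indications, "indications")

  structure(list(
    n_reports = as.integer(n_reports),
    drugs = drugs, events = events, associations = associations,
    duplicate_rate = duplicate_rate, missing_rate = missing_rate,
    date_range = date_range, outcome_probs = outcome_probs,
    demographics = demographics, indications = indications,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic reporting-system configuration\n")
  cat(sprintf("  cases: %d  (duplicate rate %.2f, missing rate %.2f)\n",
              x$n_reports, x$duplicate_rate, x$missing_rate))
  cat(sprintf("  drugs: %d  events: %d  injected associations: %d\n",
              length(x$drugs), length(x$events), nrow(x$associations)))
  cat(sprintf("  receipt window: %s .. %s   seed: %d\n",
              x$date_range[1], x$date_range[2], x$seed))
  invisible(x)
}

#' Read a generator configuration from a YAML file
#'
#' Keys mirror the [generator_config()] arguments; `drugs`, `events` and
#' `associations` are YAML sequences of mappings.
#'
#' @param path YAML file path.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    n_reports = y$n_reports, drugs = y$drugs, events = y$events,
    associations = y$associations, seed = y$seed %||% 1L
  )
  if (!is.null(y$duplicate_rate)) args$duplicate_rate <- y$duplicate_rate
  if (!is.null(y$missing_rate)) args$missing_rate <- y$missing_rate
  if (!is.null(y$date_range)) args$date_range <- as.Date(unlist(y$date_range))
  if (!is.null(y$outcome_probs)) args$outcome_probs <- unlist(y$outcome_probs)
  if (!is.null(y$demographics)) {
    d <- .default_demographics
    for (nm in names(y$demographics)) d[[nm]] <- unlist(y$demographics[[nm]])
    args$demographics <- d
  }
  if (!is.null(y$indications)) args$indications <- unlist(y$indications)
  do.call(generator_config, args)
}

.sample_cat <- function(n, dist) {
  sample(names(dist), n, replace = TRUE, prob = dist)
}

.age_from_group <- function(groups) {
  lo <- c("<18" = 1, "18-44" = 18, "45-64" = 45, "65-74" = 65,
          "75-84" = 75, ">85" = 85)
  hi <- c("<18" = 17, "18-44" = 44, "45-64" = 64, "65-74" = 74,
          "75-84" = 84, ">85" = 99)
  n <- length(groups)
  floor(stats::runif(n, lo[groups], hi[groups] + 1))
}

#' Generate a synthetic FAERS-style bundle
#'
#' Draws one reporting-system realisation under the configured margins and
#' associations. Every case yields one demographic record per report
#' version; duplicated cases replicate their drug/reaction/outcome rows under
#' a second report identifier with a distinct (earlier first version)
#' receipt date. Each report carries one non-target background suspect drug,
#' the exposed target drugs as primary/secondary suspects, reaction
#' preferred terms drawn per event, outcome codes, therapy dates and
#' indication records. Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A validated [faers_bundle()].
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_reports
  drug_ids <- vapply(config$drugs, `[[`, character(1), "id")
  p_use <- vapply(config$drugs, function(d) as.numeric(d$p_use), numeric(1))
  event_terms <- vapply(config$events, `[[`, character(1), "term")
  p_event <- vapply(config$events, function(e) as.numeric(e$p), numeric(1))
  nd <- length(drug_ids)
  ne <- length(event_terms)

  # exposure and event occurrence
  exposed <- matrix(stats::runif(n * nd) < rep(p_use, each = n), n, nd)
  rate <- matrix(rep(p_event, each = n), n, ne)
  if (nrow(config$associations) > 0) {
    for (k in seq_len(nrow(config$associations))) {
      j <- match(config$associations$drug_id[k], drug_ids)
      e <- match(config$associations$event[k], event_terms)
      rate[exposed[, j], e] <- rate[exposed[, j], e] * config$associations$rr[k]
    }
  }
  rate <- pmin(rate, 1)
  occurred <- matrix(stats::runif(n * ne), n, ne) < rate

  # case-level attributes
  caseid <- sprintf("%08d", seq_len(n))
  span <- as.integer(config$date_range[2] - config$date_range[1])
  receipt <- config$date_range[1] + sample.int(span + 1L, n, replace = TRUE) - 1L
  sex <- .sample_cat(n, config$demographics$sex)
  age_group <- .sample_cat(n, config$demographics$age_group)
  age <- .age_from_group(age_group)
  # infants reported in months, a sliver of adults in decades
  age_cod <- rep("YR", n)
  infant <- age < 2 & stats::runif(n) < 0.5
  age[infant] <- pmax(1, age[infant] * 12L)
  age_cod[infant] <- "MON"
  country <- .sample_cat(n, config$demographics$country)
  occp <- ifelse(.sample_cat(n, config$demographics$reporter) ==
                   "health-professional", "MD", "CN")
  if (config$missing_rate > 0) {
    blank <- function(x) {
      x[stats::runif(n) < config$missing_rate] <- ""
      x
    }
    sex <- blank(sex)
    country <- blank(country)
    occp <- blank(occp)
    drop_age <- stats::runif(n) < config$missing_rate
    age[drop_age] <- NA
    age_cod[drop_age] <- ""
  }

  # report versions: duplicated cases get an earlier first version
  dup <- stats::runif(n) < config$duplicate_rate
  n_versions <- 1L + dup
  case_idx <- rep(seq_len(n), n_versions)           # ordered by case
  version <- sequence(n_versions)                   # 1 or 1,2 per case
  # within a case the later version has the larger primaryid
  primaryid <- sprintf("%09d", seq_along(case_idx))
  v_receipt <- receipt[case_idx]
  first_of_dup <- version == 1L & dup[case_idx]
  v_receipt[first_of_dup] <- pmax(
    config$date_range[1],
    v_receipt[first_of_dup] - sample.int(365L, sum(first_of_dup),
                                         replace = TRUE)
  )

  demo <- tibble::tibble(
    primaryid = primaryid,
    caseid = caseid[case_idx],
    fda_dt = format(v_receipt, "%Y%m%d"),
    event_dt = format(v_receipt - 30L, "%Y%m%d"),
    sex = sex[case_idx],
    age = ifelse(is.na(age[case_idx]), "", as.character(age[case_idx])),
    age_cod = age_cod[case_idx],
    reporter_country = country[case_idx],
    occp_cod = occp[case_idx]
  )

  # per-case drug rows: one background suspect + exposed targets
  bg_name <- sample(.background_drugs, n, replace = TRUE)
  target_rows <- which(exposed, arr.ind = TRUE)  # (case, drug) pairs
  target_rows <- target_rows[order(target_rows[, 1], target_rows[, 2]), ,
                             drop = FALSE]
  syn_pick <- function(j, k) {
    syns <- config$drugs[[j]]$synonyms
    syns[k %% length(syns) + 1L]
  }
  t_case <- target_rows[, 1]
  t_drug <- target_rows[, 2]
  t_name <- toupper(vapply(seq_along(t_drug),
                           function(i) syn_pick(t_drug[i], i), character(1)))
  # sequence numbers: background drug is seq 1, targets follow
  t_seq <- stats::ave(t_case, t_case, FUN = seq_along) + 1L
  t_role <- ifelse(t_seq == 2L, "PS", "SS")
  case_drug <- tibble::tibble(
    case = c(seq_len(n), t_case),
    drug_seq = c(rep(1L, n), as.integer(t_seq)),
    role_cod = c(rep("PS", n), t_role),
    drugname = c(bg_name, t_name),
    prod_ai = c(rep("", n), drug_ids[t_drug]),
    is_target = c(rep(FALSE, n), rep(TRUE, length(t_case)))
  )
  case_drug <- case_drug[order(case_drug$case, case_drug$drug_seq), ]

  # per-case reaction rows; reports with no sampled event get a filler PT
  ev_rows <- which(occurred, arr.ind = TRUE)
  has_event <- rowSums(occurred) > 0
  filler_case <- which(!has_event)
  case_reac <- tibble::tibble(
    case = c(ev_rows[, 1], filler_case),
    pt = c(event_terms[ev_rows[, 2]],
           sample(.background_pts, length(filler_case), replace = TRUE))
  )
  case_reac <- case_reac[order(case_reac$case), ]

  # outcome codes, independent Bernoulli per code
  oc <- names(config$outcome_probs)
  oc_mat <- matrix(stats::runif(n * length(oc)), n, length(oc)) <
    rep(config$outcome_probs, each = n)
  oc_rows <- which(oc_mat, arr.ind = TRUE)
  case_outc <- tibble::tibble(case = oc_rows[, 1], outc_cod = oc[oc_rows[, 2]])
  case_outc <- case_outc[order(case_outc$case), ]

  # indication + therapy rows for target-drug records
  tgt <- case_drug[case_drug$is_target, ]
  indi_terms <- .sample_cat(nrow(tgt), config$indications)
  case_indi <- tibble::tibble(
    case = c(case_drug$case[!case_drug$is_target], tgt$case),
    indi_drug_seq = c(case_drug$drug_seq[!case_drug$is_target], tgt$drug_seq),
    indi_pt = c(rep("Product used for unknown indication",
                    sum(!case_drug$is_target)), indi_terms)
  )
  case_indi <- case_indi[order(case_indi$case, case_indi$indi_drug_seq), ]
  ther_start <- receipt[tgt$case] -
    sample.int(720L, nrow(tgt), replace = TRUE) - 30L
  case_ther <- tibble::tibble(
    case = tgt$case,
    dsg_drug_seq = tgt$drug_seq,
    start_dt = format(ther_start, "%Y%m%d"),
    end_dt = ""
  )

  # replicate child rows once per report version of their case
  replicate_children <- function(t) {
    reps <- n_versions[t$case]
    out <- t[rep(seq_len(nrow(t)), reps), , drop = FALSE]
    # primaryid of each replicated row: version offset within the case block
    first_pid_idx <- match(out$case, case_idx)
    ver <- sequence(reps)
    out$primaryid <- primaryid[first_pid_idx + ver - 1L]
    out$case <- NULL
    out[c("primaryid", setdiff(names(out), "primaryid"))]
  }
  drug <- replicate_children(case_drug)
  drug$is_target <- NULL
  drug$drug_seq <- as.character(drug$drug_seq)
  reac <- replicate_children(case_reac)
  outc <- replicate_children(case_outc)
  indi <- replicate_children(case_indi)
  indi$indi_drug_seq <- as.character(indi$indi_drug_seq)
  ther <- replicate_children(case_ther)
  ther$dsg_drug_seq <- as.character(ther$dsg_drug_seq)

  faers_bundle(demo = demo, drug = drug, reac = reac, outc = outc,
               ther = ther, indi = indi)
}

#' Closed-form expected contingency cells under the configuration
#'
#' For every declared (drug, event) pair, the expected cells of the 2x2
#' table under the configured margins: `E[a] = n p_drug min(1, p_event RR)`,
#' the remaining cells by subtraction from the margins. Exact when at most
#' one target drug is associated with a given event (co-occurring associated
#' drugs multiply rates in the generator but are ignored here).
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per (drug, event) pair: `drug_id`, `event`,
#'   `rr`, expected cells `ea`, `eb`, `ec`, `ed` (summing to `n_reports`),
#'   and `expected_ror`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_reports
  grid <- expand.grid(
    drug_id = vapply(config$drugs, `[[`, character(1), "id"),
    event = vapply(config$events, `[[`, character(1), "term"),
    stringsAsFactors = FALSE
  )
  p_use <- stats::setNames(vapply(config$drugs, function(d)
    as.numeric(d$p_use), numeric(1)),
    vapply(config$drugs, `[[`, character(1), "id"))
  p_ev <- stats::setNames(vapply(config$events, function(e)
    as.numeric(e$p), numeric(1)),
    vapply(config$events, `[[`, character(1), "term"))
  rr <- rep(1, nrow(grid))
  if (nrow(config$associations) > 0) {
    key <- paste(grid$drug_id, grid$event, sep = "\r")
    akey <- paste(config$associations$drug_id, config$associations$event,
                  sep = "\r")
    hit <- match(key, akey)
    rr[!is.na(hit)] <- config$associations$rr[hit[!is.na(hit)]]
  }
  pd <- unname(p_use[grid$drug_id])
  pe <- unname(p_ev[grid$event])
  ea <- n * pd * pmin(1, pe * rr)
  ec <- n * pd - ea
  eb <- n * (1 - pd) * pe
  ed <- n - ea - eb - ec
  tibble::tibble(
    drug_id = grid$drug_id, event = grid$event, rr = rr,
    ea = ea, eb = eb, ec = ec, ed = ed,
    expected_ror = ifelse(eb * ec > 0, (ea * ed) / (eb * ec), NA_real_)
  )
}
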