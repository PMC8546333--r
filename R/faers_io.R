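# Quarterly ASCII dialect: six '$'-delimited tables with one header row.
# The current dialect keys reports by PRIMARYID/CASEID; the legacy dialect
# (pre-2012Q4 releases) by ISR/CASE. Both are normalized onto the current
# column names at read time. All bundle columns are kept as character so a
# write/read cycle is exact; typed views (dates, ages) are derived by the
# case pipeline.

.faers_tables <- c("demo", "drug", "reac", "outc", "ther", "indi")

.faers_schema <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
           "age_cod", "reporter_country", "occp_cod"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt")
)

.legacy_map <- c(isr = "primaryid", "case" = "caseid")

.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
.role_codes <- c("PS", "SS", "C", "I")

#' Assemble a FAERS-style bundle from its six tables
#'
#' Validates the schema and referential integrity of the six linked report
#' tables. All columns are character; missing values are empty strings.
#'
#' @param demo,drug,reac,outc,ther,indi Data frames following the quarterly
#'   ASCII column layout (`primaryid`, `caseid`, `fda_dt`, ... for `demo`;
#'   see the package vignette for the full schema). Extra columns are
#'   preserved.
#' @return A `faers_bundle`: a named list of six tibbles.
#' @export
faers_bundle <- function(demo, drug = NULL, reac = NULL, outc = NULL,
                         ther = NULL, indi = NULL) {
  empty <- function(tab) {
    tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(.faers_schema[[tab]])),
      .faers_schema[[tab]]
    ))
  }
  tabs <- list(demo = demo, drug = drug, reac = reac, outc = outc,
               ther = ther, indi = indi)
  for (nm in .faers_tables) {
    if (is.null(tabs[[nm]])) {
      tabs[[nm]] <- empty(nm)
      next
    }
    t <- tibble::as_tibble(tabs[[nm]])
    need <- .faers_schema[[nm]]
    miss <- setdiff(need, names(t))
    if (length(miss) > 0) {
      stop(sprintf("%s table is missing column(s): %s", toupper(nm),
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    t[] <- lapply(t, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- ""
      col
    })
    # required columns first, opaque extras after
    tabs[[nm]] <- t[c(need, setdiff(names(t), need))]
  }
  bundle <- structure(tabs, class = "faers_bundle")
  validate_bundle(bundle)
  bundle
}

#' Validate a FAERS bundle
#'
#' Checks referential integrity (every child `primaryid` appears in `demo`),
#' the controlled vocabularies (role codes, outcome codes), non-empty
#' reaction terms, and that receipt dates parse as (possibly partial)
#' calendar dates.
#'
#' @param bundle A `faers_bundle`.
#' @return `bundle`, invisibly; errors describe the first violation found.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "faers_bundle"))
  ids <- bundle$demo$primaryid
  if (anyDuplicated(ids)) {
    stop("duplicate primaryid in DEMO", call. = FALSE)
  }
  for (nm in setdiff(.faers_tables, "demo")) {
    orphan <- setdiff(bundle[[nm]]$primaryid, ids)
    if (length(orphan) > 0) {
      stop(sprintf("%s references primaryid(s) absent from DEMO: %s",
                   toupper(nm), paste(utils::head(orphan, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad_role <- setdiff(unique(bundle$drug$role_cod), c(.role_codes, ""))
  if (length(bad_role) > 0) {
    stop("unknown drug role code(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  bad_outc <- setdiff(unique(bundle$outc$outc_cod), c(.outcome_codes, ""))
  if (length(bad_outc) > 0) {
    stop("unknown outcome code(s): ", paste(bad_outc, collapse = ", "),
         call. = FALSE)
  }
  if (any(bundle$reac$pt == "")) {
    stop("REAC contains empty preferred terms", call. = FALSE)
  }
  dt <- parse_faers_date(bundle$demo$fda_dt)
  bad_dt <- bundle$demo$fda_dt != "" & is.na(dt$date)
  if (any(bad_dt)) {
    stop("DEMO contains unparseable FDA_DT value(s): ",
         paste(utils::head(unique(bundle$demo$fda_dt[bad_dt]), 5),
               collapse = ", "), call. = FALSE)
  }
  if (any(bundle$demo$fda_dt == "")) {
    stop("DEMO contains missing FDA_DT (receipt date is required)",
         call. = FALSE)
  }
  invisible(bundle)
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("FAERS-style report bundle\n")
  for (nm in .faers_tables) {
    cat(sprintf("  %s: %6d rows\n", toupper(nm), nrow(x[[nm]])))
  }
  cat(sprintf("  distinct cases: %d\n", length(unique(x$demo$caseid))))
  invisible(x)
}

#' Parse FAERS date strings
#'
#' Accepts full `YYYYMMDD`, partial `YYYYMM` and `YYYY` forms. Partial dates
#' are flagged and completed with the earliest possible components
#' (January / day 1), so ordering by available precision treats missing
#' components as earliest. Anything else parses to `NA`.
#'
#' @param x Character vector of date strings ("" = missing).
#' @return A list with `date` (class `Date`) and `partial` (logical).
#' @export
parse_faers_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  full <- ifelse(grepl("^[0-9]{8}$", x), x,
          ifelse(grepl("^[0-9]{6}$", x), paste0(x, "01"),
          ifelse(grepl("^[0-9]{4}$", x), paste0(x, "0101"), NA_character_)))
  list(date = as.Date(full, format = "%Y%m%d"),
       partial = !is.na(full) & nchar(x) < 8)
}

.find_table_file <- function(directory, table) {
  files <- list.files(directory, full.names = TRUE)
  hits <- files[grepl(paste0("^", table), basename(files), ignore.case = TRUE)]
  hits <- hits[!dir.exists(hits)]
  if (length(hits) == 0) {
    stop(sprintf("no %s file found in %s", toupper(table), directory),
         call. = FALSE)
  }
  sort(hits)[1]
}

.read_dollar_file <- function(path, tolerance) {
  nf <- utils::count.fields(path, sep = "$", quote = "\"", comment.char = "")
  if (length(nf) == 0) {
    stop("file is empty (no header): ", path, call. = FALSE)
  }
  n_cols <- nf[1]
  body <- nf[-1]
  bad <- which(!is.na(body) & body != n_cols)
  n_body <- length(body)
  if (length(bad) > 0 && n_body > 0 && length(bad) / n_body > tolerance) {
    stop(sprintf(
      "%s: %d of %d data rows malformed (line%s %s) exceeds tolerance %.3f",
      basename(path), length(bad), n_body, if (length(bad) > 1) "s" else "",
      paste(utils::head(bad + 1L, 10), collapse = ", "), tolerance),
      call. = FALSE)
  }
  src <- path
  if (length(bad) > 0) {
    message(sprintf("%s: dropped %d malformed row(s)", basename(path),
                    length(bad)))
    lines <- readLines(path, encoding = "UTF-8")
    src <- textConnection(lines[-(bad + 1L)])
    on.exit(close(src), add = TRUE)
  }
  t <- utils::read.table(src, sep = "$", quote = "\"", header = TRUE,
                         colClasses = "character", comment.char = "",
                         na.strings = character(0), check.names = FALSE,
                         blank.lines.skip = FALSE,
                         encoding = "UTF-8")
  names(t) <- tolower(names(t))
  tibble::as_tibble(t)
}

#' Read one quarter of FAERS-style ASCII tables
#'
#' Locates the six `$`-delimited files (by case-insensitive table-name
#' prefix: `DEMO*`, `DRUG*`, ...) in a directory, parses them, normalizes
#' legacy `ISR`/`CASE` identifiers onto `primaryid`/`caseid`, and returns a
#' validated bundle. Malformed rows (wrong field count) are dropped with a
#' message while their fraction stays within `tolerance`; above it the read
#' fails with the offending line numbers.
#'
#' @param directory Directory holding the six files.
#' @param dialect `"auto"` (default: header inspection — an `ISR` column
#'   marks the legacy dialect), `"current"`, or `"legacy"`.
#' @param tolerance Maximum tolerated fraction of malformed data rows per
#'   file (default 0).
#' @return A validated [faers_bundle()].
#' @export
read_quarter <- function(directory, dialect = c("auto", "current", "legacy"),
                         tolerance = 0) {
  dialect <- match.arg(dialect)
  if (!dir.exists(directory)) {
    stop("directory not found: ", directory, call. = FALSE)
  }
  tabs <- list()
  for (nm in .faers_tables) {
    t <- .read_dollar_file(.find_table_file(directory, nm), tolerance)
    is_legacy <- switch(dialect,
      legacy = TRUE,
      current = FALSE,
      auto = "isr" %in% names(t)
    )
    if (is_legacy) {
      hit <- names(t) %in% names(.legacy_map)
      names(t)[hit] <- .legacy_map[names(t)[hit]]
      # legacy drug_seq column names match the current ones already;
      # older INDI/THER releases used DRUG_SEQ for the child sequence too
      if (nm == "ther" && "drug_seq" %in% names(t) &&
          !"dsg_drug_seq" %in% names(t)) {
        names(t)[names(t) == "drug_seq"] <- "dsg_drug_seq"
      }
      if (nm == "indi" && "drug_seq" %in% names(t) &&
          !"indi_drug_seq" %in% names(t)) {
        names(t)[names(t) == "drug_seq"] <- "indi_drug_seq"
      }
    }
    tabs[[nm]] <- t
  }
  faers_bundle(demo = tabs$demo, drug = tabs$drug, reac = tabs$reac,
               outc = tabs$outc, ther = tabs$ther, indi = tabs$indi)
}

#' Write a bundle as quarterly ASCII files
#'
#' Emits the six `$`-delimited files (`DEMO.txt`, `DRUG.txt`, ...) with one
#' header row each. Character values are quoted, so embedded `$` and quotes
#' round-trip exactly: `read_quarter(write_quarter(b))` reproduces `b`
#' field for field.
#'
#' @param bundle A [faers_bundle()].
#' @param directory Output directory (created if absent).
#' @return The output directory path, invisibly.
#' @export
write_quarter <- function(bundle, directory) {
  validate_bundle(bundle)
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  for (nm in .faers_tables) {
    path <- file.path(directory, paste0(toupper(nm), ".txt"))
    utils::write.table(bundle[[nm]], path, sep = "$", quote = TRUE,
                       qmethod = "double", row.names = FALSE,
                       col.names = TRUE, na = "", fileEncoding = "UTF-8")
  }
  invisible(directory)
}
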