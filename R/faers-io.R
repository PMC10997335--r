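#' File dialect for FAERS-style quarterly tables
#'
#' FAERS quarterly data files are "$"-delimited ASCII with a header row.
#' The dialect object carries the delimiter, the strings treated as missing,
#' and the header aliases accepted for each logical column, so the reader
#' also accepts comma/tab-delimited exports or renamed headers.
#'
#' @param delim Single-character field delimiter (default `"$"`, the FAERS
#'   quarterly convention).
#' @param na Character vector of strings read as missing.
#' @param aliases Optional named list overriding the default header aliases.
#'   Structure: `list(demo = list(report_id = c(...), ...), drug = ..., ...)`.
#'   Matching is case-insensitive.
#' @return A list of class `faers_dialect`.
#' @export
#' @examples
#' faers_dialect()
#' faers_dialect(delim = "\t")
faers_dialect <- function(delim = "$", na = c("", "NA"), aliases = NULL) {
  defaults <- list(
    demo = list(
      report_id    = c("isr", "primaryid", "caseid", "report_id"),
      receive_date = c("receive_date", "fda_dt", "init_fda_dt", "rept_dt"),
      age          = c("age", "age_value"),
      age_unit     = c("age_cod", "age_unit"),
      sex          = c("gndr_cod", "sex", "gender"),
      country      = c("reporter_country", "occr_country", "country")
    ),
    drug = list(
      report_id  = c("isr", "primaryid", "caseid", "report_id"),
      drug_name  = c("drugname", "drug_name", "medicinalproduct"),
      role       = c("role_cod", "role"),
      indication = c("indi_pt", "indication"),
      dose       = c("dose_mg", "dose_amt", "daily_dose_mg")
    ),
    reac = list(
      report_id = c("isr", "primaryid", "caseid", "report_id"),
      pt        = c("pt", "preferred_term")
    ),
    outc = list(
      report_id = c("isr", "primaryid", "caseid", "report_id"),
      outcome   = c("outc_cod", "outc_code", "outcome")
    )
  )
  if (!is.null(aliases)) {
    for (tab in names(aliases)) {
      for (fld in names(aliases[[tab]])) {
        defaults[[tab]][[fld]] <- unique(c(tolower(aliases[[tab]][[fld]]),
                                           defaults[[tab]][[fld]]))
      }
    }
  }
  structure(list(delim = delim, na = na, aliases = defaults),
            class = "faers_dialect")
}

# fields that must be present in the header of each table
.required_fields <- list(
  demo = c("report_id", "receive_date"),
  drug = c("report_id", "drug_name"),
  reac = c("report_id", "pt"),
  outc = c("report_id", "outcome")
)

.role_codes <- c("primary_suspect", "secondary_suspect", "concomitant",
                 "interacting", "unknown")

.outcome_codes <- c("death", "life_threatening", "hospitalization",
                    "disability", "congenital_anomaly", "other")

#' Parse FAERS-style dates
#'
#' Accepts `YYYYMMDD` and ISO `YYYY-MM-DD`; anything else is `NA`.
#'
#' @param x Character vector.
#' @return `Date` vector.
#' @keywords internal
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  out <- as.Date(rep(NA_character_, length(x)))
  compact <- !is.na(x) & grepl("^\\d{8}$", x)
  iso <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[compact] <- suppressWarnings(as.Date(x[compact], format = "%Y%m%d"))
  out[iso] <- suppressWarnings(as.Date(x[iso]))
  out
}

# map header names of a raw table onto logical field names; error on an
# unknown layout, naming the observed header
resolve_columns <- function(raw, table_name, dialect) {
  aliases <- dialect$aliases[[table_name]]
  hdr <- tolower(names(raw))
  out <- tibble::tibble(.rows = nrow(raw))
  for (fld in names(aliases)) {
    hit <- which(hdr %in% aliases[[fld]])
    if (length(hit)) {
      out[[fld]] <- as.character(raw[[hit[1]]])
    } else {
      out[[fld]] <- NA_character_
    }
  }
  missing_req <- setdiff(.required_fields[[table_name]],
                         names(aliases)[vapply(names(aliases), function(f)
                           any(hdr %in% aliases[[f]]), logical(1))])
  if (length(missing_req)) {
    stop(sprintf(
      "table '%s': unknown column layout; required field(s) %s not found among header: %s",
      table_name, paste(missing_req, collapse = ", "),
      paste(names(raw), collapse = ", ")), call. = FALSE)
  }
  out
}

quarantine_tbl <- function(table, rows, reasons, report_ids) {
  tibble::tibble(table = table, row = rows, report_id = report_ids,
                 reason = reasons)
}

parse_demo_table <- function(raw) {
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  rid <- trimws(raw$report_id)
  reason[is.na(rid) | !nzchar(rid)] <- "missing report_id"

  date <- parse_faers_date(raw$receive_date)
  bad_date <- is.na(date)
  reason[is.na(reason) & bad_date & is.na(raw$receive_date)] <- "missing receive_date"
  reason[is.na(reason) & bad_date] <- "unparseable receive_date"
  out_of_range <- !bad_date & (date < as.Date("1990-01-01") | date > Sys.Date())
  reason[is.na(reason) & out_of_range] <- "receive_date out of range"

  age_raw <- raw$age
  age_num <- suppressWarnings(as.numeric(age_raw))
  reason[is.na(reason) & !is.na(age_raw) & is.na(age_num)] <- "unparseable age"
  reason[is.na(reason) & !is.na(age_num) & age_num < 0] <- "negative age"
  unit <- canon_str(raw$age_unit)
  factor_map <- c(yr = 1, year = 1, years = 1,
                  mon = 1 / 12, month = 1 / 12, months = 1 / 12,
                  dy = 1 / 365.25, day = 1 / 365.25, days = 1 / 365.25)
  fac <- unname(factor_map[unit])
  fac[is.na(unit)] <- 1            # unit absent: value taken as years
  reason[is.na(reason) & !is.na(age_num) & !is.na(unit) & is.na(factor_map[unit])] <-
    "unknown age unit"
  age_years <- age_num * fac

  sex_c <- canon_str(raw$sex)
  sex <- dplyr::case_when(
    sex_c %in% c("m", "male") ~ "male",
    sex_c %in% c("f", "female") ~ "female",
    .default = "unknown"
  )
  country <- toupper(trimws(raw$country))
  country[!is.na(country) & !nzchar(country)] <- NA_character_

  ok <- is.na(reason)
  list(
    accepted = tibble::tibble(
      report_id = rid, receive_date = date, age_years = age_years,
      sex = sex, country = country)[ok, ],
    quarantined = quarantine_tbl("demo", which(!ok), reason[!ok], rid[!ok])
  )
}

parse_drug_table <- function(raw) {
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  rid <- trimws(raw$report_id)
  reason[is.na(rid) | !nzchar(rid)] <- "missing report_id"

  name <- canon_str(raw$drug_name)
  reason[is.na(reason) & is.na(name)] <- "missing drug name"

  role_c <- canon_str(raw$role)
  role <- dplyr::case_when(
    role_c %in% c("ps", "primary suspect", "primary_suspect") ~ "primary_suspect",
    role_c %in% c("ss", "secondary suspect", "secondary_suspect") ~ "secondary_suspect",
    role_c %in% c("c", "concomitant") ~ "concomitant",
    role_c %in% c("i", "interacting") ~ "interacting",
    .default = "unknown"                       # unrecognized codes retained
  )

  dose <- suppressWarnings(as.numeric(raw$dose))
  reason[is.na(reason) & !is.na(raw$dose) & is.na(dose)] <- "unparseable dose"
  reason[is.na(reason) & !is.na(dose) & dose <= 0] <- "non-positive dose"

  indication <- canon_str(raw$indication)

  ok <- is.na(reason)
  list(
    accepted = tibble::tibble(
      report_id = rid, drug_name_raw = name, role = role,
      indication = indication, daily_dose_mg = dose)[ok, ],
    quarantined = quarantine_tbl("drug", which(!ok), reason[!ok], rid[!ok])
  )
}

parse_reac_table <- function(raw) {
  reason <- rep(NA_character_, nrow(raw))
  rid <- trimws(raw$report_id)
  reason[is.na(rid) | !nzchar(rid)] <- "missing report_id"
  pt <- canon_str(raw$pt)
  reason[is.na(reason) & is.na(pt)] <- "missing preferred term"
  ok <- is.na(reason)
  list(
    accepted = tibble::tibble(report_id = rid, pt = pt)[ok, ],
    quarantined = quarantine_tbl("reac", which(!ok), reason[!ok], rid[!ok])
  )
}

parse_outc_table <- function(raw) {
  reason <- rep(NA_character_, nrow(raw))
  rid <- trimws(raw$report_id)
  reason[is.na(rid) | !nzchar(rid)] <- "missing report_id"
  oc <- canon_str(raw$outcome)
  outcome <- dplyr::case_when(
    oc %in% c("de", "death") ~ "death",
    oc %in% c("lt", "life-threatening", "life threatening", "life_threatening") ~ "life_threatening",
    oc %in% c("ho", "hospitalization", "hospitalisation") ~ "hospitalization",
    oc %in% c("ds", "disability") ~ "disability",
    oc %in% c("ca", "congenital anomaly", "congenital_anomaly") ~ "congenital_anomaly",
    .default = "other"
  )
  reason[is.na(reason) & is.na(oc)] <- "missing outcome code"
  ok <- is.na(reason)
  list(
    accepted = tibble::tibble(report_id = rid, outcome = outcome)[ok, ],
    quarantined = quarantine_tbl("outc", which(!ok), reason[!ok], rid[!ok])
  )
}

#' Assemble a validated report bundle from in-memory raw tables
#'
#' The workhorse behind [read_quarter()], exposed so that generated tables
#' can enter the pipeline without a file round trip. Rows that violate a
#' record invariant (bad dates, negative ages, non-positive doses, blank
#' keys) are quarantined with a reason, never silently dropped; records in
#' the drug/reaction/outcome tables whose report ID is absent from the
#' accepted demographics are quarantined as orphans (or rejected outright).
#'
#' @param tables Named list with elements `demo`, `drug`, `reac`, `outc`,
#'   each a data frame of character columns as read from file.
#' @param dialect A [faers_dialect()] (used for header aliases).
#' @param orphan_policy `"quarantine"` (default) or `"error"`.
#' @return A `faers_bundle`: list with tibbles `demographics`, `drugs`,
#'   `reactions`, `outcomes`, a `quarantine` tibble (table, row, report_id,
#'   reason), and a `counts` tibble with per-table input/accepted/quarantined
#'   row counts.
#' @export
bundle_tables <- function(tables, dialect = faers_dialect(),
                          orphan_policy = c("quarantine", "error")) {
  orphan_policy <- match.arg(orphan_policy)
  need <- c("demo", "drug", "reac", "outc")
  missing_tab <- setdiff(need, names(tables))
  if (length(missing_tab)) {
    stop("missing table(s): ", paste(missing_tab, collapse = ", "),
         call. = FALSE)
  }
  parsed <- list(
    demo = parse_demo_table(resolve_columns(tables$demo, "demo", dialect)),
    drug = parse_drug_table(resolve_columns(tables$drug, "drug", dialect)),
    reac = parse_reac_table(resolve_columns(tables$reac, "reac", dialect)),
    outc = parse_outc_table(resolve_columns(tables$outc, "outc", dialect))
  )
  if (nrow(parsed$demo$accepted) == 0) {
    stop("demographics table has no valid rows after validation", call. = FALSE)
  }

  known <- unique(parsed$demo$accepted$report_id)
  for (tab in c("drug", "reac", "outc")) {
    acc <- parsed[[tab]]$accepted
    orphan <- !(acc$report_id %in% known)
    if (any(orphan)) {
      if (orphan_policy == "error") {
        stop(sprintf("table '%s': %d record(s) reference unknown report IDs",
                     tab, sum(orphan)), call. = FALSE)
      }
      parsed[[tab]]$quarantined <- dplyr::bind_rows(
        parsed[[tab]]$quarantined,
        quarantine_tbl(tab, which(orphan), "orphan report_id",
                       acc$report_id[orphan]))
      parsed[[tab]]$accepted <- acc[!orphan, ]
    }
  }

  n_in <- vapply(tables[need], nrow, integer(1))
  counts <- tibble::tibble(
    table = need,
    n_input = as.integer(unname(n_in)),
    n_accepted = unname(vapply(parsed, function(p) nrow(p$accepted), integer(1))),
    n_quarantined = unname(vapply(parsed, function(p) nrow(p$quarantined), integer(1)))
  )
  structure(
    list(
      demographics = parsed$demo$accepted,
      drugs = parsed$drug$accepted,
      reactions = parsed$reac$accepted,
      outcomes = parsed$outc$accepted,
      quarantine = dplyr::bind_rows(lapply(parsed, `[[`, "quarantined")),
      counts = counts
    ),
    class = "faers_bundle"
  )
}

#' Read one set of FAERS-style quarterly tables
#'
#' Reads the four report tables (demographics, drug records, reaction
#' records, outcome records) from delimited text and validates them into a
#' report bundle. Loading is lossless modulo quarantine: for every table,
#' accepted rows + quarantined rows = input rows.
#'
#' @param paths Named character vector or list with elements `demo`, `drug`,
#'   `reac`, `outc` giving the file path of each table.
#' @param dialect A [faers_dialect()].
#' @inheritParams bundle_tables
#' @return A `faers_bundle`; see [bundle_tables()].
#' @export
#' @examples
#' cfg <- synthetic_config(n_background_reports = 300, n_study_reports = 80,
#'                         seed = 1)
#' dir <- tempfile(); dir.create(dir)
#' generate_faers(cfg, dir)
#' b <- read_quarter(quarter_paths(dir))
#' b
read_quarter <- function(paths, dialect = faers_dialect(),
                         orphan_policy = c("quarantine", "error")) {
  need <- c("demo", "drug", "reac", "outc")
  missing_tab <- setdiff(need, names(paths))
  if (length(missing_tab)) {
    stop("no path given for table(s): ", paste(missing_tab, collapse = ", "),
         call. = FALSE)
  }
  for (tab in need) {
    if (!file.exists(paths[[tab]])) {
      stop(sprintf("table '%s': file not found: %s", tab, paths[[tab]]),
           call. = FALSE)
    }
  }
  raw <- lapply(need, function(tab) {
    readr::read_delim(paths[[tab]], delim = dialect$delim, na = dialect$na,
                      col_types = readr::cols(.default = readr::col_character()),
                      show_col_types = FALSE, progress = FALSE)
  })
  names(raw) <- need
  bundle_tables(raw, dialect = dialect, orphan_policy = orphan_policy)
}

#' Standard file names of the four tables under a directory
#'
#' @param dir Directory holding `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `OUTC.txt` (the layout written by [generate_faers()]).
#' @return Named character vector usable as `paths` in [read_quarter()].
#' @export
quarter_paths <- function(dir) {
  c(demo = file.path(dir, "DEMO.txt"), drug = file.path(dir, "DRUG.txt"),
    reac = file.path(dir, "REAC.txt"), outc = file.path(dir, "OUTC.txt"))
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("<faers_bundle>\n")
  cat(sprintf("  demographics: %d  drugs: %d  reactions: %d  outcomes: %d\n",
              nrow(x$demographics), nrow(x$drugs), nrow(x$reactions),
              nrow(x$outcomes)))
  cat(sprintf("  quarantined rows: %d\n", nrow(x$quarantine)))
  invisible(x)
}

#' Write a result table as delimited text
#'
#' Tab-separated with a header row; written values round-trip through
#' [readr::read_tsv()] without loss.
#'
#' @param rows A data frame with a uniform schema.
#' @param path Output file path.
#' @param delim Field delimiter (default tab).
#' @return The path, invisibly.
#' @export
write_table <- function(rows, path, delim = "\t") {
  if (!is.data.frame(rows)) stop("'rows' must be a data frame", call. = FALSE)
  tryCatch(
    readr::write_delim(rows, path, delim = delim, na = "NA", progress = FALSE),
    error = function(e) stop("cannot write table to '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}
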