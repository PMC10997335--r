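#' Canonical names of the five study drugs
#'
#' The triazole antifungal agents the worked analysis targets. Any drug list
#' can be passed to the pipeline functions; this is the default.
#'
#' @return Character vector of five canonical generic names.
#' @export
study_drugs <- function() {
  c("fluconazole", "voriconazole", "itraconazole", "posaconazole",
    "isavuconazole")
}

#' Load a drug synonym table
#'
#' @param path Two-column delimited file (raw name, canonical generic name).
#' @param delim Field delimiter (default tab).
#' @return Tibble with columns `raw_name` (canonicalized), `canonical`.
#' @export
load_synonyms <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("synonym table not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) stop("synonym table must have two columns", call. = FALSE)
  tibble::tibble(raw_name = canon_str(raw[[1]]), canonical = canon_str(raw[[2]]))
}

# match one canonical raw name against the synonym table: exact match first,
# then the longest token prefix ("vfend 200mg tab" -> "vfend"); deterministic,
# no fuzzy matching
match_drug_name <- function(names_canon, synonyms) {
  out <- synonyms$canonical[match(names_canon, synonyms$raw_name)]
  todo <- which(is.na(out) & !is.na(names_canon))
  for (i in todo) {
    toks <- strsplit(names_canon[i], " ", fixed = TRUE)[[1]]
    for (k in rev(seq_along(toks))) {
      if (k == length(toks)) next   # full string already tried
      cand <- paste(toks[seq_len(k)], collapse = " ")
      hit <- match(cand, synonyms$raw_name)
      if (!is.na(hit)) { out[i] <- synonyms$canonical[hit]; break }
    }
  }
  out
}

#' Normalize raw drug names to canonical study drugs
#'
#' Maps free-text drug names (brands, salts, dose-suffixed strings) to the
#' canonical generic names via the synonym table: exact case-folded match
#' first, then the longest token-prefix match. Unmatched records are
#' retained with their (canonicalized) raw name and flagged non-study.
#'
#' @param drugs Tibble of drug records with a `drug_name_raw` column.
#' @param synonyms Synonym tibble from [load_synonyms()] /
#'   [fixture_synonyms()].
#' @return `drugs` with added columns `drug` (canonical name, or raw name if
#'   unmatched) and `is_study` (matched a synonym entry).
#' @export
#' @examples
#' d <- tibble::tibble(drug_name_raw = c("DIFLUCAN", "VFEND 200MG TAB", "ASPIRIN"))
#' normalize_drug_names(d, fixture_synonyms())
normalize_drug_names <- function(drugs, synonyms) {
  stopifnot("drug_name_raw" %in% names(drugs))
  uniq <- unique(canon_str(drugs$drug_name_raw))
  hit <- match_drug_name(uniq, synonyms)
  canon <- canon_str(drugs$drug_name_raw)
  mapped <- hit[match(canon, uniq)]
  drugs$drug <- dplyr::coalesce(mapped, canon)
  drugs$is_study <- !is.na(mapped)
  drugs
}

# fields of the 8-field duplicate key: adverse event, report ID, receive
# date, drug, indication, sex, country, age
dedup_key_fields <- function() {
  c("pt", "report_id", "receive_date", "drug", "indication", "sex",
    "country", "age_years")
}

#' Remove duplicate reports
#'
#' Two case rows are duplicates when they agree on all eight key fields
#' (adverse event PT, report ID, receive date, drug, indication, sex,
#' reporter country, age); missing equals missing, so two reports both
#' lacking age can still be duplicates. The earliest-loaded row of each
#' equivalence class survives (stable), making runs reproducible.
#'
#' @param cases Case tibble carrying the key fields.
#' @param key Character vector of key columns (default the 8-field key).
#' @return Deduplicated tibble; attribute `n_removed` holds the count of
#'   removed rows.
#' @export
deduplicate <- function(cases, key = dedup_key_fields()) {
  missing_key <- setdiff(key, names(cases))
  if (length(missing_key)) {
    stop("case table lacks duplicate-key field(s): ",
         paste(missing_key, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::distinct(cases, dplyr::across(dplyr::all_of(key)),
                         .keep_all = TRUE)
  attr(out, "n_removed") <- nrow(cases) - nrow(out)
  out
}

#' Keep primary-suspect records only
#'
#' Drops case rows whose drug role is interacting, concomitant, secondary
#' suspect or unknown, leaving the reports in which the drug was judged the
#' primary suspect for the event.
#'
#' @param cases Case tibble with a `role` column.
#' @return Filtered tibble; attribute `n_removed` holds the removed count.
#' @export
filter_primary_suspect <- function(cases) {
  stopifnot("role" %in% names(cases))
  out <- cases[!is.na(cases$role) & cases$role == "primary_suspect", ]
  attr(out, "n_removed") <- nrow(cases) - nrow(out)
  out
}

#' Flatten a report bundle into one row per (report, drug, PT) case
#'
#' Joins distinct drug rows with distinct reaction rows per report and then
#' the demographics. Because exact duplicate submissions share the report ID
#' and all record content, taking distinct drug/reaction rows and joining
#' every demographics row restores exactly one case row per submission: a
#' report submitted k times yields k identical case rows (removed down to
#' one by [deduplicate()]), while a single report with several drugs and
#' reactions yields their ordinary cross product.
#'
#' @param bundle A `faers_bundle`.
#' @param synonyms Synonym table for drug-name normalization.
#' @return Case tibble: `report_id`, `drug`, `drug_name_raw`, `is_study`,
#'   `role`, `indication`, `daily_dose_mg`, `pt`, `receive_date`,
#'   `receive_year`, `age_years`, `sex`, `country`, `outcomes` (list-column
#'   of the report's distinct outcome codes).
#' @export
flatten_bundle <- function(bundle, synonyms) {
  stopifnot(inherits(bundle, "faers_bundle"))
  drugs <- normalize_drug_names(bundle$drugs, synonyms)
  drugs <- dplyr::distinct(drugs)
  reac <- dplyr::distinct(bundle$reactions)
  outc <- dplyr::distinct(bundle$outcomes)
  outc_sets <- dplyr::summarise(
    dplyr::group_by(outc, .data$report_id),
    outcomes = list(sort(unique(.data$outcome))), .groups = "drop")

  flat <- dplyr::inner_join(drugs, reac, by = "report_id",
                            relationship = "many-to-many")
  flat <- dplyr::inner_join(flat, bundle$demographics, by = "report_id",
                            relationship = "many-to-many")
  flat <- dplyr::left_join(flat, outc_sets, by = "report_id")
  flat$outcomes[vapply(flat$outcomes, is.null, logical(1))] <- list(character(0))
  flat$receive_year <- as.integer(format(flat$receive_date, "%Y"))
  flat
}

#' Screen study-drug cases through the full funnel
#'
#' The screening flow applied to each quarter set: extract study-drug case
#' rows within the study window, restrict to the target SOC, deduplicate on
#' the 8-field key, then keep primary-suspect records. Per-stage counts are
#' returned as the audit funnel; each stage only removes rows, so counts are
#' monotonically non-increasing.
#'
#' @param bundle A `faers_bundle`.
#' @param map A `pt_soc_map`.
#' @param synonyms Synonym table.
#' @param soc_name Target SOC (default `"Cardiac disorders"`).
#' @param window Two integers, first and last receive year kept (default
#'   `c(2004, 2022)`).
#' @param drugs Canonical study drug names (default [study_drugs()]).
#' @return A `faers_cases` object: list with `cases` (the final case
#'   tibble) and `funnel` (tibble of stage, n, n_removed).
#' @export
build_cases <- function(bundle, map, synonyms, soc_name = "Cardiac disorders",
                        window = c(2004L, 2022L), drugs = study_drugs()) {
  flat <- flatten_bundle(bundle, synonyms)
  extracted <- flat[flat$is_study & flat$drug %in% drugs &
                      !is.na(flat$receive_year) &
                      flat$receive_year >= window[1] &
                      flat$receive_year <= window[2], ]
  cardiac <- filter_cardiac(extracted, map, soc_name)
  deduped <- deduplicate(cardiac)
  ps <- filter_primary_suspect(deduped)
  funnel <- tibble::tibble(
    stage = c("extracted", "soc_restricted", "deduplicated", "primary_suspect"),
    n = c(nrow(extracted), nrow(cardiac), nrow(deduped), nrow(ps)),
    n_removed = c(NA_integer_, nrow(extracted) - nrow(cardiac),
                  nrow(cardiac) - nrow(deduped), nrow(deduped) - nrow(ps))
  )
  structure(list(cases = ps, funnel = funnel), class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases> screening funnel\n")
  print(x$funnel)
  invisible(x)
}

#' Build the full analysis universe for disproportionality
#'
#' The disproportionality background is every deduplicated primary-suspect
#' case row in the database — all drugs and all events, not only the study
#' drugs or the target SOC — within the study window.
#'
#' @inheritParams build_cases
#' @return Case tibble (all drugs, all PTs), deduplicated and PS-filtered.
#' @export
build_universe <- function(bundle, synonyms, window = c(2004L, 2022L)) {
  flat <- flatten_bundle(bundle, synonyms)
  flat <- flat[!is.na(flat$receive_year) & flat$receive_year >= window[1] &
                 flat$receive_year <= window[2], ]
  filter_primary_suspect(deduplicate(flat))
}
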