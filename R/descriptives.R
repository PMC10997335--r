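.serious_outcomes <- c("death", "life_threatening", "hospitalization",
                       "disability", "congenital_anomaly")

#' Default outcome severity priority
#'
#' When a report carries several outcome codes, a single category is
#' assigned by this priority (most severe first), so that per-drug outcome
#' rows sum to the drug's report total. The standard FAERS convention;
#' configurable in the functions that use it.
#'
#' @return Character vector of the six outcome categories, most severe
#'   first.
#' @export
outcome_priority <- function() {
  c("death", "life_threatening", "hospitalization", "disability",
    "congenital_anomaly", "other")
}

#' Named regions used in the reporting-region breakdown
#' @return Character vector of country codes broken out individually;
#'   everything else is pooled as "Other countries".
#' @export
region_levels <- function() {
  c(US = "United States", JP = "Japan", CN = "China", FR = "France",
    GB = "United Kingdom", DE = "Germany", CA = "Canada")
}

#' Routine daily doses of the study drugs
#'
#' Label-recommended routine daily dosage in mg: fluconazole 400,
#' voriconazole 400, posaconazole 300, itraconazole 200, isavuconazole 200.
#'
#' @return Tibble with columns `drug`, `routine_mg`.
#' @export
routine_dose_map <- function() {
  tibble::tibble(
    drug = c("fluconazole", "voriconazole", "posaconazole", "itraconazole",
             "isavuconazole"),
    routine_mg = c(400, 400, 300, 200, 200)
  )
}

# collapse case rows (one per report-drug-PT) to one row per (report, drug),
# keeping demographics and the outcome set
collapse_reports <- function(cases) {
  keep <- intersect(c("report_id", "drug", "receive_year", "receive_date",
                      "age_years", "sex", "country", "daily_dose_mg",
                      "outcomes"), names(cases))
  dplyr::distinct(cases[, keep], .data$report_id, .data$drug,
                  .keep_all = TRUE)
}

# single-category outcome assignment by severity priority
assign_outcome <- function(outcome_sets, priority = outcome_priority()) {
  vapply(outcome_sets, function(s) {
    if (length(s) == 0) return("other")
    hit <- priority[priority %in% s]
    if (length(hit)) hit[1] else "other"
  }, character(1))
}

#' Summarize clinical characteristics of screened reports
#'
#' Per-drug and total breakdowns of sex, age (mean over reported ages,
#' "not reported" counted separately), reporting region, and
#' single-assignment outcome categories, computed on one row per
#' (report, drug).
#'
#' @param cases Case tibble (deduplicated, PS-filtered).
#' @param priority Outcome severity priority, see [outcome_priority()].
#' @param regions Named regions, see [region_levels()].
#' @return A `faers_characteristics` list with tibbles `sex`, `age`,
#'   `region`, `outcome`, and scalar `n_total`.
#' @export
summarize_characteristics <- function(cases, priority = outcome_priority(),
                                      regions = region_levels()) {
  rep_tbl <- collapse_reports(cases)
  n_total <- nrow(rep_tbl)

  sex_tbl <- dplyr::count(rep_tbl, .data$drug,
                          sex = dplyr::if_else(.data$sex %in% c("male", "female"),
                                               .data$sex, "not_reported"))
  sex_tbl <- tidyr::complete(sex_tbl, .data$drug,
                             sex = c("male", "female", "not_reported"),
                             fill = list(n = 0L))

  age_tbl <- dplyr::summarise(
    dplyr::group_by(rep_tbl, .data$drug),
    mean_age = mean(.data$age_years, na.rm = TRUE),
    n_reported = sum(!is.na(.data$age_years)),
    n_not_reported = sum(is.na(.data$age_years)), .groups = "drop")

  region <- dplyr::if_else(rep_tbl$country %in% names(regions),
                           unname(regions[rep_tbl$country]),
                           "Other countries")
  region[is.na(rep_tbl$country)] <- "Other countries"
  region_tbl <- dplyr::count(
    tibble::tibble(drug = rep_tbl$drug, region = region),
    .data$drug, .data$region)

  outcome_tbl <- dplyr::count(
    tibble::tibble(drug = rep_tbl$drug,
                   outcome = assign_outcome(rep_tbl$outcomes, priority)),
    .data$drug, .data$outcome)
  outcome_tbl <- tidyr::complete(outcome_tbl, .data$drug,
                                 outcome = priority, fill = list(n = 0L))

  structure(
    list(sex = sex_tbl, age = age_tbl, region = region_tbl,
         outcome = outcome_tbl, n_total = n_total,
         mean_age_total = mean(rep_tbl$age_years, na.rm = TRUE)),
    class = "faers_characteristics")
}

#' @export
print.faers_characteristics <- function(x, ...) {
  cat(sprintf("<faers_characteristics> %d reports, mean age %.2f\n",
              x$n_total, x$mean_age_total))
  invisible(x)
}

#' Serious-outcome counts and shares per drug
#'
#' A report counts as serious when any of its outcome codes is death,
#' life-threatening, hospitalization, disability or congenital anomaly;
#' the share is serious reports over the drug's report total, as a
#' percentage rounded half-up to 2 decimals. A `Total` row is appended.
#'
#' @param cases Case tibble (deduplicated, PS-filtered) with an `outcomes`
#'   list-column.
#' @return Tibble with columns `drug`, `n_reports`, `n_serious`,
#'   `share_pct`.
#' @export
serious_outcome_share <- function(cases) {
  rep_tbl <- collapse_reports(cases)
  rep_tbl$serious <- vapply(rep_tbl$outcomes,
                            function(s) any(s %in% .serious_outcomes),
                            logical(1))
  per_drug <- dplyr::summarise(
    dplyr::group_by(rep_tbl, .data$drug),
    n_reports = dplyr::n(), n_serious = sum(.data$serious),
    .groups = "drop")
  total <- tibble::tibble(drug = "Total",
                          n_reports = nrow(rep_tbl),
                          n_serious = sum(rep_tbl$serious))
  out <- dplyr::bind_rows(per_drug, total)
  out$share_pct <- pct(out$n_serious, out$n_reports)
  out
}

#' Share of reports assigned each outcome category
#'
#' Single-assignment outcome counts over all reports, with the share of the
#' grand total — e.g. the share of all screened reports whose assigned
#' outcome is hospitalization.
#'
#' @inheritParams serious_outcome_share
#' @param priority Outcome severity priority.
#' @return Tibble with columns `outcome`, `n`, `share_pct`.
#' @export
outcome_share <- function(cases, priority = outcome_priority()) {
  rep_tbl <- collapse_reports(cases)
  out <- dplyr::count(
    tibble::tibble(outcome = assign_outcome(rep_tbl$outcomes, priority)),
    .data$outcome)
  out <- tidyr::complete(out, outcome = priority, fill = list(n = 0L))
  out$share_pct <- pct(out$n, nrow(rep_tbl))
  out[match(priority, out$outcome), ]
}

#' Yearly report counts per drug
#'
#' Counts of (report, drug) rows by receive year, in wide per-drug layout,
#' with each year's total and its percentage of the grand total (rounded
#' half-up to 2 decimals). Years outside the window are excluded with a
#' warning.
#'
#' @param cases Case tibble with `receive_year`.
#' @param window Two integers, first and last year kept.
#' @param drugs Column order for the per-drug counts.
#' @return Tibble with columns `year`, one column per drug, `total`,
#'   `total_pct`.
#' @export
yearly_counts <- function(cases, window = c(2004L, 2022L),
                          drugs = study_drugs()) {
  rep_tbl <- collapse_reports(cases)
  outside <- !is.na(rep_tbl$receive_year) &
    (rep_tbl$receive_year < window[1] | rep_tbl$receive_year > window[2])
  if (any(outside)) {
    warning(sum(outside), " report(s) outside the study window excluded")
    rep_tbl <- rep_tbl[!outside, ]
  }
  grand <- nrow(rep_tbl)
  long <- dplyr::count(rep_tbl, year = .data$receive_year, .data$drug)
  wide <- tidyr::pivot_wider(long, names_from = "drug", values_from = "n",
                             values_fill = 0L)
  for (d in setdiff(drugs, names(wide))) wide[[d]] <- 0L
  wide <- wide[, c("year", intersect(drugs, names(wide)),
                   setdiff(names(wide), c("year", drugs)))]
  wide <- dplyr::arrange(wide, .data$year)
  count_cols <- setdiff(names(wide), "year")
  wide$total <- as.integer(rowSums(wide[, count_cols, drop = FALSE]))
  wide$total_pct <- pct(wide$total, grand)
  wide
}

#' Daily-dose analysis against routine dosage
#'
#' Among reports with a known daily dose, counts how many did not exceed
#' the drug's routine daily dosage (a dose exactly equal to routine counts
#' as not exceeding). Reports with missing dose are counted separately;
#' non-positive doses never reach this function (quarantined at load).
#'
#' @param cases Case tibble with `daily_dose_mg`.
#' @param routine Routine dose tibble, see [routine_dose_map()].
#' @return Tibble with columns `drug`, `n_reports`, `n_known`,
#'   `n_at_or_below`, `share_pct` (`NA` when no dose is known).
#' @export
dose_analysis <- function(cases, routine = routine_dose_map()) {
  rep_tbl <- collapse_reports(cases)
  rep_tbl <- dplyr::left_join(rep_tbl, routine, by = "drug")
  out <- dplyr::summarise(
    dplyr::group_by(rep_tbl, .data$drug),
    n_reports = dplyr::n(),
    n_known = sum(!is.na(.data$daily_dose_mg)),
    n_at_or_below = sum(!is.na(.data$daily_dose_mg) &
                          .data$daily_dose_mg <= .data$routine_mg),
    .groups = "drop")
  out$share_pct <- pct(out$n_at_or_below, out$n_known)
  out
}

#' Report-distribution shares from per-drug totals
#'
#' Given per-drug totals of all adverse-event reports, the cardiac subset
#' and the deduplicated primary-suspect subset, computes each drug's share
#' of the three column totals and the two headline ratios: the cardiac
#' share of all study-drug reports and the primary-suspect share of the
#' cardiac reports (percentages rounded half-up to 2 decimals).
#'
#' @param counts Tibble like [fixture_table1()] with columns `drug`,
#'   `taa_ae_n`, `cardiac_ae_n`, `ps_n`.
#' @return List with `table` (per-drug counts plus `*_pct` share columns),
#'   `cardiac_share_of_taa` and `ps_share_of_cardiac`.
#' @export
summarize_distribution <- function(counts) {
  stopifnot(all(c("drug", "taa_ae_n", "cardiac_ae_n", "ps_n") %in%
                  names(counts)))
  tot <- vapply(counts[, c("taa_ae_n", "cardiac_ae_n", "ps_n")], sum,
                numeric(1))
  tab <- counts
  tab$taa_ae_pct <- pct(tab$taa_ae_n, tot[["taa_ae_n"]])
  tab$cardiac_ae_pct <- pct(tab$cardiac_ae_n, tot[["cardiac_ae_n"]])
  tab$ps_pct <- pct(tab$ps_n, tot[["ps_n"]])
  list(
    table = tab,
    totals = tot,
    cardiac_share_of_taa = pct(tot[["cardiac_ae_n"]], tot[["taa_ae_n"]]),
    ps_share_of_cardiac = pct(tot[["ps_n"]], tot[["cardiac_ae_n"]])
  )
}
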