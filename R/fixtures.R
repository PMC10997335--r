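#' @keywords internal
fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "faersignal")
  if (!nzchar(p)) stop("packaged fixture not found: ", name, call. = FALSE)
  p
}

#' Packaged PT-to-SOC fixture map
#'
#' A small PT-to-SOC map covering every distinct cardiac-disorders PT that
#' appears in the published triazole-antifungal signal table, plus a set of
#' non-cardiac decoy PTs across other SOCs. It stands in for the licensed
#' MedDRA dictionary in examples and tests; supply your own map via
#' [load_pt_soc_map()] for real analyses.
#'
#' @return A `pt_soc_map`.
#' @export
fixture_pt_soc <- function() {
  load_pt_soc_map(fixture_path("pt_soc_fixture.tsv"),
                  version_label = "packaged cardiac-SOC fixture")
}

#' Packaged drug synonym fixture
#'
#' Brand names, salt forms and common spelling variants of the five triazole
#' antifungal agents, mapping each to its canonical generic name.
#'
#' @return Tibble with columns `raw_name`, `canonical`.
#' @export
fixture_synonyms <- function() {
  readr::read_tsv(fixture_path("drug_synonyms.tsv"),
                  col_types = "cc", progress = FALSE)
}

#' Transcribed published signal-strength table
#'
#' The published PT-level signal table for triazole-antifungal-associated
#' cardiac adverse events: per (drug, PT) the report count and the printed
#' ROR and PRR point estimates with their 95% CI bounds, transcribed
#' verbatim (including two rows whose printed ROR/PRR columns are internally
#' inconsistent in the source). Used to replay the dual signal criteria
#' against published numbers.
#'
#' @return Tibble with columns `drug`, `pt`, `n`, `ror`, `ror_low`,
#'   `ror_high`, `prr`, `prr_low`, `prr_high`.
#' @export
#' @examples
#' tab <- fixture_table4()
#' dplyr::count(tab, drug)
fixture_table4 <- function() {
  readr::read_tsv(fixture_path("table4_signal_strength.tsv"),
                  col_types = "ccidddddd", progress = FALSE)
}

#' Published per-drug report distribution counts
#'
#' Per study drug: all adverse-event reports attributed to the drug, the
#' cardiac subset, and the cardiac subset with the drug as primary suspect
#' after deduplication.
#'
#' @return Tibble with columns `drug`, `taa_ae_n`, `cardiac_ae_n`, `ps_n`.
#' @export
fixture_table1 <- function() {
  readr::read_tsv(fixture_path("table1_report_distribution.tsv"),
                  col_types = "ciii", progress = FALSE)
}

#' Published per-drug outcome category counts
#'
#' Single-assignment outcome counts (one category per report) for the
#' deduplicated primary-suspect cardiac reports of each study drug.
#'
#' @return Tibble with columns `drug`, `outcome`, `n`.
#' @export
fixture_table2_outcomes <- function() {
  readr::read_tsv(fixture_path("table2_outcome_counts.tsv"),
                  col_types = "cci", progress = FALSE)
}

#' Published yearly report counts per drug
#'
#' @return Tibble with columns `year`, then one count column per study drug.
#' @export
fixture_table3 <- function() {
  readr::read_tsv(fixture_path("table3_yearly_counts.tsv"),
                  col_types = "iiiiii", progress = FALSE)
}

#' Expand published outcome counts into pseudo case rows
#'
#' Turns the per-drug outcome category counts into one case row per report
#' (synthetic report IDs, the assigned outcome as the report's outcome set),
#' so that the descriptive operations can be replayed on published counts.
#'
#' @param counts Tibble like [fixture_table2_outcomes()].
#' @return Case tibble with columns `report_id`, `drug`, `outcomes`
#'   (list-column).
#' @export
fixture_table2_cases <- function(counts = fixture_table2_outcomes()) {
  long <- tidyr::uncount(counts, weights = .data$n)
  tibble::tibble(
    report_id = sprintf("T2-%06d", seq_len(nrow(long))),
    drug = long$drug,
    outcomes = as.list(long$outcome)
  )
}

#' Expand published yearly counts into pseudo case rows
#'
#' @param counts Tibble like [fixture_table3()] (wide, one column per drug).
#' @return Case tibble with columns `report_id`, `drug`, `receive_year`.
#' @export
fixture_table3_cases <- function(counts = fixture_table3()) {
  long <- tidyr::pivot_longer(counts, -"year", names_to = "drug",
                              values_to = "n")
  long <- tidyr::uncount(long, weights = .data$n)
  tibble::tibble(
    report_id = sprintf("T3-%06d", seq_len(nrow(long))),
    drug = long$drug,
    receive_year = as.integer(long$year)
  )
}
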