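#' Build the 2x2 contingency table for one drug-event pair
#'
#' Against the full analysis universe (all drugs, all events), the four
#' cells are: `a` reports with the target drug and target event, `b` with
#' the target drug and any other event, `c` with any other drug and the
#' target event, `d` with any other drug and any other event. The counting
#' unit for a drug's total (`a + b`) is distinct (report, drug) pairs, so a
#' report contributes once to a drug total even when it lists several
#' non-target events; `a` and `c` count distinct reports carrying the
#' (drug, event) match.
#'
#' @param universe Case tibble from [build_universe()] (columns `report_id`,
#'   `drug`, `pt`).
#' @param drug Canonical drug name.
#' @param pt Preferred term (any case).
#' @return One-row tibble: `drug`, `pt`, `a`, `b`, `c`, `d`. A drug or PT
#'   absent from the universe gives `a = 0`, not an error.
#' @export
#' @examples
#' u <- tibble::tibble(report_id = as.character(1:4),
#'                     drug = c("d", "d", "f", "f"),
#'                     pt = c("e", "x", "e", "x"))
#' build_contingency(u, "d", "e")  # a = b = c = d = 1
build_contingency <- function(universe, drug, pt) {
  pt_c <- canon_str(pt)
  pairs <- dplyr::distinct(universe[, c("report_id", "drug")])
  n_total <- nrow(pairs)
  n_drug <- sum(pairs$drug == drug)
  is_event <- canon_str(universe$pt) == pt_c
  a <- dplyr::n_distinct(universe$report_id[universe$drug == drug & is_event])
  event_pairs <- dplyr::distinct(
    universe[is_event & universe$drug != drug, c("report_id", "drug")])
  cc <- nrow(event_pairs)
  tibble::tibble(drug = drug, pt = pt_c,
                 a = as.integer(a),
                 b = as.integer(n_drug - a),
                 c = as.integer(cc),
                 d = as.integer(n_total - n_drug - cc))
}

# optionally apply the Haldane-Anscombe 0.5 continuity correction to tables
# with a zero cell
haldane_adjust <- function(tbl, haldane) {
  if (!haldane) return(tbl)
  zero <- tbl$a == 0 | tbl$b == 0 | tbl$c == 0 | tbl$d == 0
  for (cell in c("a", "b", "c", "d")) {
    tbl[[cell]] <- tbl[[cell]] + 0.5 * zero
  }
  tbl
}

#' Reporting odds ratio with 95 percent confidence interval
#'
#' `ROR = (a/b) / (c/d)`, the odds of the target event among the target
#' drug's reports relative to those odds among all other drugs. The CI is
#' log-normal: `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. The ROR
#' is undefined when `b` or `c` is zero (the statistic's known zero-cell
#' failure mode) and, with the continuity correction off, when `a` or `d`
#' is zero; undefined results are flagged with a reason, not corrected away.
#'
#' @param tbl Tibble with integer columns `a`, `b`, `c`, `d` (one row per
#'   drug-event pair); vectorized over rows.
#' @param z Normal quantile for the CI (default 1.96, a 95% interval).
#' @param haldane If `TRUE`, add 0.5 to every cell of tables containing a
#'   zero before estimation (off by default).
#' @return `tbl` with added columns `ror`, `ror_low`, `ror_high`,
#'   `ror_defined`, `ror_reason`.
#' @export
#' @examples
#' ror(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
ror <- function(tbl, z = 1.96, haldane = FALSE) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tbl)))
  adj <- haldane_adjust(tbl[, c("a", "b", "c", "d")], haldane)
  a <- adj$a; b <- adj$b; cc <- adj$c; d <- adj$d
  reason <- dplyr::case_when(
    b == 0 | cc == 0 ~ "zero-cell b or c",
    a == 0 ~ "zero target cell a",
    d == 0 ~ "zero background cell d",
    .default = NA_character_
  )
  ok <- is.na(reason)
  est <- low <- high <- rep(NA_real_, nrow(tbl))
  est[ok] <- (a[ok] * d[ok]) / (b[ok] * cc[ok])
  se <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / cc[ok] + 1 / d[ok])
  low[ok] <- exp(log(est[ok]) - z * se)
  high[ok] <- exp(log(est[ok]) + z * se)
  tbl$ror <- est
  tbl$ror_low <- low
  tbl$ror_high <- high
  tbl$ror_defined <- ok
  tbl$ror_reason <- reason
  tbl
}

#' Proportional reporting ratio with 95 percent confidence interval
#'
#' `PRR = (a/(a+b)) / (c/(c+d))`, the proportion of the target drug's
#' reports that mention the target event relative to that proportion among
#' all other drugs. The CI is
#' `exp(log(PRR) +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. Unlike the
#' ROR, the PRR is still computable when `c` is zero — the estimate is
#' infinite and flagged, with no CI; it is undefined when `a` is zero.
#'
#' @inheritParams ror
#' @return `tbl` with added columns `prr`, `prr_low`, `prr_high`,
#'   `prr_defined`, `prr_reason`. Rows with `c = 0, a > 0` carry
#'   `prr = Inf`, `prr_defined = TRUE` and reason `"zero c: infinite"`.
#' @export
#' @examples
#' prr(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
prr <- function(tbl, z = 1.96, haldane = FALSE) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tbl)))
  adj <- haldane_adjust(tbl[, c("a", "b", "c", "d")], haldane)
  a <- adj$a; b <- adj$b; cc <- adj$c; d <- adj$d
  reason <- dplyr::case_when(
    a == 0 ~ "zero target cell a",
    (cc + d) == 0 ~ "empty background",
    cc == 0 ~ "zero c: infinite",
    .default = NA_character_
  )
  finite <- is.na(reason)
  infinite <- !is.na(reason) & reason == "zero c: infinite"
  est <- low <- high <- rep(NA_real_, nrow(tbl))
  est[finite] <- (a[finite] / (a[finite] + b[finite])) /
    (cc[finite] / (cc[finite] + d[finite]))
  se <- sqrt(1 / a[finite] - 1 / (a[finite] + b[finite]) +
               1 / cc[finite] - 1 / (cc[finite] + d[finite]))
  low[finite] <- exp(log(est[finite]) - z * se)
  high[finite] <- exp(log(est[finite]) + z * se)
  est[infinite] <- Inf
  tbl$prr <- est
  tbl$prr_low <- low
  tbl$prr_high <- high
  tbl$prr_defined <- finite | infinite
  tbl$prr_reason <- reason
  tbl
}

#' Chi-squared statistic of the 2x2 table
#'
#' Computed with [stats::chisq.test()]; the Yates-corrected variant is the
#' one used in the classic PRR signal criterion, the uncorrected variant is
#' reported alongside so the choice is visible.
#'
#' @inheritParams ror
#' @param correct Apply the Yates continuity correction (default `TRUE`).
#' @return Numeric vector of chi-squared statistics (one per row); `NA` for
#'   degenerate tables (a zero row or column margin).
#' @export
chi_square <- function(tbl, correct = TRUE) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tbl)))
  vapply(seq_len(nrow(tbl)), function(i) {
    m <- matrix(c(tbl$a[i], tbl$b[i], tbl$c[i], tbl$d[i]), nrow = 2,
                byrow = TRUE)
    tryCatch(
      unname(suppressWarnings(stats::chisq.test(m, correct = correct))$statistic),
      error = function(e) NA_real_)
  }, numeric(1))
}

#' Signal criteria configuration
#'
#' The dual-criteria rule: a drug-event pair is a signal when the report
#' count and both disproportionality statistics clear their thresholds.
#' Defaults are the canonical published criteria — at least 3 reports, ROR
#' lower 95% CI above 1, and PRR at least 2 with Yates chi-squared at
#' least 4. The chi-squared gate can be disabled (`use_chi2 = FALSE`) when
#' replaying published tables that do not print the statistic.
#'
#' @param a_min Minimum report count (default 3).
#' @param ror_low_min ROR lower CI bound must exceed this (default 1).
#' @param prr_min Minimum PRR (default 2).
#' @param chi2_min Minimum Yates chi-squared (default 4).
#' @param use_chi2 Whether the chi-squared gate applies (default `TRUE`).
#' @return A list of class `signal_criteria`.
#' @export
signal_criteria <- function(a_min = 3, ror_low_min = 1, prr_min = 2,
                            chi2_min = 4, use_chi2 = TRUE) {
  stopifnot(a_min >= 0, ror_low_min > 0, prr_min > 0, chi2_min >= 0)
  structure(list(a_min = a_min, ror_low_min = ror_low_min,
                 prr_min = prr_min, chi2_min = chi2_min,
                 use_chi2 = isTRUE(use_chi2)),
            class = "signal_criteria")
}

#' Apply the dual signal criteria
#'
#' Evaluates the criteria on a table of computed (or transcribed)
#' statistics. An undefined statistic (`NA`) fails its criterion — a pair
#' whose ROR could not be computed is never flagged.
#'
#' @param results Tibble with columns `n` (report count), `ror_low`, `prr`,
#'   and, when the chi-squared gate is active, `chi2_yates`.
#' @param criteria A [signal_criteria()].
#' @return `results` with added logical columns `meets_n`, `meets_ror`,
#'   `meets_prr`, `is_signal`.
#' @export
#' @examples
#' apply_criteria(tibble::tibble(n = 3, ror_low = 1.2, prr = 2.5,
#'                               chi2_yates = 5))
apply_criteria <- function(results, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  need <- c("n", "ror_low", "prr")
  if (criteria$use_chi2) need <- c(need, "chi2_yates")
  missing_col <- setdiff(need, names(results))
  if (length(missing_col)) {
    stop("results lack column(s): ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  }
  meets_n <- !is.na(results$n) & results$n >= criteria$a_min
  meets_ror <- !is.na(results$ror_low) & results$ror_low > criteria$ror_low_min
  meets_prr <- !is.na(results$prr) & results$prr >= criteria$prr_min
  if (criteria$use_chi2) {
    meets_prr <- meets_prr & !is.na(results$chi2_yates) &
      results$chi2_yates >= criteria$chi2_min
  }
  results$meets_n <- meets_n
  results$meets_ror <- meets_ror
  results$meets_prr <- meets_prr
  results$is_signal <- meets_n & meets_ror & meets_prr
  results
}

# vectorized contingency cells for every (drug in drugs) x (pt observed with
# that drug); algebraically identical to build_contingency row by row
contingency_grid <- function(universe, drugs) {
  pairs <- dplyr::distinct(universe[, c("report_id", "drug")])
  n_total <- nrow(pairs)
  drug_tot <- dplyr::count(pairs, .data$drug, name = "n_drug")
  upt <- universe
  upt$pt <- canon_str(upt$pt)
  cell <- dplyr::summarise(
    dplyr::group_by(upt, .data$drug, .data$pt),
    a = dplyr::n_distinct(.data$report_id), .groups = "drop")
  pt_pairs <- dplyr::distinct(upt[, c("report_id", "drug", "pt")])
  pt_tot <- dplyr::count(dplyr::distinct(pt_pairs),
                         .data$pt, name = "n_pt_pairs")
  grid <- cell[cell$drug %in% drugs, ]
  grid <- dplyr::left_join(grid, drug_tot, by = "drug")
  grid <- dplyr::left_join(grid, pt_tot, by = "pt")
  grid$b <- grid$n_drug - grid$a
  grid$c <- grid$n_pt_pairs - grid$a
  grid$d <- n_total - grid$n_drug - grid$c
  grid[, c("drug", "pt", "a", "b", "c", "d")]
}

#' Full signal table for a set of study drugs
#'
#' For every (study drug, target-SOC PT) pair observed at least once,
#' builds the 2x2 table against the universe, computes ROR, PRR and both
#' chi-squared variants, and applies the dual criteria. Rows are sorted per
#' drug by descending ROR.
#'
#' @param universe Case tibble from [build_universe()].
#' @param drugs Canonical study drug names (default [study_drugs()]).
#' @param map A `pt_soc_map`; only PTs mapping to `soc_name` are scored.
#' @param soc_name Target SOC (default `"Cardiac disorders"`).
#' @param criteria A [signal_criteria()].
#' @param signals_only Keep only flagged rows (default `FALSE`: all scored
#'   pairs are returned with their `is_signal` flag).
#' @param haldane Continuity-correction policy passed to [ror()]/[prr()].
#' @return Tibble with one row per scored pair: `drug`, `pt`, `n`, the four
#'   cells, `ror`/`prr` estimates with CI bounds and definedness flags,
#'   `chi2`, `chi2_yates`, criteria flags and `is_signal`.
#' @export
signal_table <- function(universe, drugs = study_drugs(), map,
                         soc_name = "Cardiac disorders",
                         criteria = signal_criteria(), signals_only = FALSE,
                         haldane = FALSE) {
  grid <- contingency_grid(universe, drugs)
  soc <- pt_soc(grid$pt, map)
  grid <- grid[!is.na(soc) & soc == soc_name & grid$a >= 1, ]
  if (nrow(grid) == 0) {
    empty <- tibble::tibble(
      drug = character(), pt = character(), a = integer(), b = integer(),
      c = integer(), d = integer())
    empty <- prr(ror(empty))
    empty$n <- integer(0)
    empty$chi2 <- numeric(0)
    empty$chi2_yates <- numeric(0)
    return(apply_criteria(empty, criteria))
  }
  res <- ror(grid, haldane = haldane)
  res <- prr(res, haldane = haldane)
  res$n <- res$a
  res$chi2 <- chi_square(grid, correct = FALSE)
  res$chi2_yates <- chi_square(grid, correct = TRUE)
  res <- apply_criteria(res, criteria)
  res <- dplyr::arrange(res, factor(.data$drug, levels = drugs),
                        dplyr::desc(.data$ror))
  if (signals_only) res <- res[res$is_signal, ]
  res
}
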