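#' Run the full screening and signal-detection pipeline
#'
#' Orchestrates generate/load -> screen -> describe -> signal and writes
#' every result table as tab-separated text under `out_dir`: the screening
#' funnel audit (`funnel.tsv`), demographics (`characteristics_*.tsv`),
#' serious outcomes (`serious_outcomes.tsv`), yearly counts
#' (`yearly_counts.tsv`), the dose analysis (`dose_analysis.tsv`) and the
#' signal table (`signal_table.tsv`). Per-stage counts are logged with
#' [message()]. With a synthetic input and fixed seed two runs produce
#' identical output files.
#'
#' @param input Either a directory containing the four quarterly tables
#'   (see [quarter_paths()]) or a [synthetic_config()] to generate one.
#' @param out_dir Output directory (created if needed).
#' @param pt_soc_path Path to a PT-SOC map; `NULL` uses the packaged
#'   fixture.
#' @param synonyms_path Path to a drug synonym table; `NULL` uses the
#'   packaged fixture.
#' @param soc_name Target SOC.
#' @param window Study window (first and last receive year).
#' @param criteria A [signal_criteria()].
#' @param drugs Canonical study drug names.
#' @param dialect A [faers_dialect()].
#' @return Invisibly, a list with the screened `cases`, `funnel`,
#'   `universe`, the descriptive tables, the `signals` table and the output
#'   `paths`.
#' @export
run_pipeline <- function(input, out_dir,
                         pt_soc_path = NULL, synonyms_path = NULL,
                         soc_name = "Cardiac disorders",
                         window = c(2004L, 2022L),
                         criteria = signal_criteria(),
                         drugs = study_drugs(),
                         dialect = faers_dialect()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  map <- tryCatch({
    if (is.null(pt_soc_path)) fixture_pt_soc()
    else load_pt_soc_map(pt_soc_path)
  }, error = function(e) stop_stage("meddra_map", conditionMessage(e)))
  synonyms <- tryCatch({
    if (is.null(synonyms_path)) fixture_synonyms()
    else load_synonyms(synonyms_path)
  }, error = function(e) stop_stage("synonyms", conditionMessage(e)))

  if (inherits(input, "synthetic_config")) {
    in_dir <- file.path(out_dir, "input")
    tryCatch(generate_faers(input, in_dir),
             error = function(e) stop_stage("generate", conditionMessage(e)))
    message("[generate] wrote synthetic tables to ", in_dir)
    input <- in_dir
  }
  bundle <- tryCatch(
    read_quarter(quarter_paths(input), dialect = dialect),
    error = function(e) stop_stage("load", conditionMessage(e)))
  message(sprintf("[load] demo=%d drug=%d reac=%d outc=%d quarantined=%d",
                  nrow(bundle$demographics), nrow(bundle$drugs),
                  nrow(bundle$reactions), nrow(bundle$outcomes),
                  nrow(bundle$quarantine)))

  screened <- tryCatch(
    build_cases(bundle, map, synonyms, soc_name = soc_name, window = window,
                drugs = drugs),
    error = function(e) stop_stage("screen", conditionMessage(e)))
  for (i in seq_len(nrow(screened$funnel))) {
    message(sprintf("[screen] %-16s n=%d", screened$funnel$stage[i],
                    screened$funnel$n[i]))
  }
  universe <- tryCatch(
    build_universe(bundle, synonyms, window = window),
    error = function(e) stop_stage("universe", conditionMessage(e)))
  message("[universe] case rows: ", nrow(universe))

  cases <- screened$cases
  chars <- summarize_characteristics(cases)
  serious <- serious_outcome_share(cases)
  yearly <- yearly_counts(cases, window = window, drugs = drugs)
  dose <- dose_analysis(cases)
  signals <- tryCatch(
    signal_table(universe, drugs = drugs, map = map, soc_name = soc_name,
                 criteria = criteria),
    error = function(e) stop_stage("signal", conditionMessage(e)))
  message(sprintf("[signal] %d pairs scored, %d signals",
                  nrow(signals), sum(signals$is_signal)))

  paths <- c(
    funnel = write_table(screened$funnel, file.path(out_dir, "funnel.tsv")),
    sex = write_table(chars$sex, file.path(out_dir, "characteristics_sex.tsv")),
    age = write_table(chars$age, file.path(out_dir, "characteristics_age.tsv")),
    region = write_table(chars$region,
                         file.path(out_dir, "characteristics_region.tsv")),
    outcome = write_table(chars$outcome,
                          file.path(out_dir, "characteristics_outcome.tsv")),
    serious = write_table(serious, file.path(out_dir, "serious_outcomes.tsv")),
    yearly = write_table(yearly, file.path(out_dir, "yearly_counts.tsv")),
    dose = write_table(dose, file.path(out_dir, "dose_analysis.tsv")),
    signals = write_table(
      dplyr::select(signals, -dplyr::any_of(c("ror_reason", "prr_reason"))),
      file.path(out_dir, "signal_table.tsv"))
  )
  invisible(list(cases = cases, funnel = screened$funnel,
                 universe = universe, characteristics = chars,
                 serious = serious, yearly = yearly, dose = dose,
                 signals = signals, paths = paths))
}
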