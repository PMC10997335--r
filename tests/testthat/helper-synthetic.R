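# Shared synthetic database for tests: generated once per test run.
# Moderate size keeps the whole suite fast while leaving the planted
# torsade-de-pointes association with a well-populated 2x2 table.

small_config <- function(seed = 42, duplicate_rate = 0.05, ...) {
  synthetic_config(
    n_background_reports = 6000,
    n_study_reports = 1500,
    planted_signals = tibble::tibble(
      drug = "fluconazole", pt = "torsade de pointes", target_ror = 40),
    duplicate_rate = duplicate_rate,
    seed = seed,
    ...
  )
}

.shared <- new.env(parent = emptyenv())

shared_gen <- function() {
  if (is.null(.shared$gen)) {
    .shared$gen <- generate_faers(small_config())
  }
  .shared$gen
}

shared_bundle <- function() {
  if (is.null(.shared$bundle)) {
    .shared$bundle <- bundle_tables(shared_gen()$tables)
  }
  .shared$bundle
}

shared_cases <- function() {
  if (is.null(.shared$cases)) {
    .shared$cases <- build_cases(shared_bundle(), fixture_pt_soc(),
                                 fixture_synonyms())
  }
  .shared$cases
}

shared_universe <- function() {
  if (is.null(.shared$universe)) {
    .shared$universe <- build_universe(shared_bundle(), fixture_synonyms())
  }
  .shared$universe
}

# write a list of tables as "$"-delimited files and return quarter paths
write_quarter_files <- function(tables, dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  fn <- c(demo = "DEMO.txt", drug = "DRUG.txt", reac = "REAC.txt",
          outc = "OUTC.txt")
  for (tab in names(fn)) {
    readr::write_delim(tables[[tab]], file.path(dir, fn[[tab]]),
                       delim = "$", na = "")
  }
  quarter_paths(dir)
}

# minimal hand-built raw tables (character columns, FAERS-like headers)
toy_tables <- function() {
  list(
    demo = tibble::tibble(
      ISR = c("A1", "A2", "A3"),
      RECEIVE_DATE = c("20180105", "20190612", "20200220"),
      AGE = c("55", "720", NA),
      AGE_COD = c("YR", "MON", NA),
      GNDR_COD = c("M", "F", NA),
      REPORTER_COUNTRY = c("US", "JP", NA)
    ),
    drug = tibble::tibble(
      ISR = c("A1", "A1", "A2", "A3"),
      DRUGNAME = c("DIFLUCAN", "ASPIRIN", "VFEND 200MG TAB", "SPORANOX"),
      ROLE_COD = c("PS", "C", "SS", "XX"),
      INDI_PT = c("candidiasis", NA, "aspergillosis", NA),
      DOSE_MG = c("400", NA, "300", "200")
    ),
    reac = tibble::tibble(
      ISR = c("A1", "A2", "A3"),
      PT = c("Torsade de pointes", "RASH", "Cardiac failure")
    ),
    outc = tibble::tibble(
      ISR = c("A1", "A2"),
      OUTC_COD = c("HO", "OT")
    )
  )
}
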