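.bg_drugs <- c("aspirin", "metformin", "lisinopril", "atorvastatin",
               "omeprazole", "amoxicillin", "ibuprofen", "warfarin",
               "furosemide", "prednisone", "amiodarone", "levothyroxine",
               "gabapentin", "sertraline", "amlodipine", "simvastatin",
               "clopidogrel", "pantoprazole", "methotrexate", "rituximab",
               "cisplatin", "paclitaxel", "tacrolimus", "cyclosporine",
               "vancomycin")

.brand_names <- c(fluconazole = "DIFLUCAN", voriconazole = "VFEND",
                  itraconazole = "SPORANOX", posaconazole = "NOXAFIL",
                  isavuconazole = "CRESEMBA")

.study_indications <- c("candidiasis", "aspergillosis", "mucormycosis",
                        "antifungal prophylaxis", "onychomycosis",
                        "cryptococcal meningitis")
.bg_indications <- c("hypertension", "pain", "infection", "diabetes mellitus",
                     "neoplasm malignant", "prophylaxis", "depression")

.country_probs <- c(US = 0.3298, JP = 0.1082, CN = 0.0919, GB = 0.0762,
                    FR = 0.0634, DE = 0.0366, CA = 0.0198, IT = 0.06,
                    ES = 0.05, BR = 0.05, IN = 0.04, AU = 0.04, KR = 0.03,
                    NL = 0.03, SE = 0.0241)

#' Configuration of the synthetic report generator
#'
#' Defines the statistical structure of a generated FAERS-like database:
#' report counts, per-drug shares, planted drug-event association
#' strengths, duplicate and missingness rates, role mix, dose model and
#' study window. Defaults emulate the screened triazole-antifungal cardiac
#' cohort: per-drug shares, sex/region mixes, age distribution, serious
#' outcome mix, missingness and over-routine dose probabilities follow the
#' published descriptive tables, with the study-drug fraction of the
#' database scaled up so drug-event cells are populated at desk scale.
#'
#' @param n_background_reports Reports for background (non-study) drugs.
#' @param n_study_reports Reports for the five study drugs combined.
#' @param study_drug_shares Named numeric, per-drug share of study reports
#'   (normalized to sum to 1).
#' @param planted_signals Tibble with columns `drug`, `pt`, `target_ror`;
#'   each row inflates the drug's event odds so the expected reporting odds
#'   ratio against the background equals `target_ror`.
#' @param cardiac_share Baseline probability that a report's event is a
#'   cardiac-SOC PT (before planting).
#' @param duplicate_rate Fraction of reports duplicated as exact copies of
#'   all records (sharing the report ID, as the same case re-submitted).
#' @param role_mix Named probabilities over the five drug role codes.
#' @param missingness Named list of per-field missingness probabilities
#'   (`age`, `sex`, `country`, `indication`, `dose`).
#' @param p_serious Probability a report carries a serious outcome code.
#' @param serious_mix Named probabilities over the five serious outcome
#'   categories, given serious.
#' @param p_exceed Named per-drug probability that a known dose exceeds the
#'   routine daily dosage (doses are drawn at 0.5/1/1.5/2 x routine).
#' @param age_mean,age_sd Age distribution (years).
#' @param start_date,end_date Receive-date range (dates sampled uniformly).
#' @param pt_cardiac,pt_other Event vocabularies; default from the packaged
#'   PT-SOC fixture (frequencies decay as 1/rank within each block).
#' @param seed Integer seed; a fixed seed makes output byte-identical.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_background_reports = 45000,
    n_study_reports = 5000,
    study_drug_shares = c(fluconazole = 0.352, voriconazole = 0.397,
                          itraconazole = 0.130, posaconazole = 0.073,
                          isavuconazole = 0.048),
    planted_signals = tibble::tibble(
      drug = c("fluconazole", "itraconazole"),
      pt = c("torsade de pointes", "cardiac failure"),
      target_ror = c(40, 6)),
    cardiac_share = 0.115,
    duplicate_rate = 0.05,
    role_mix = c(primary_suspect = 0.30, secondary_suspect = 0.25,
                 concomitant = 0.30, interacting = 0.05, unknown = 0.10),
    missingness = list(age = 0.25, sex = 0.129, country = 0.05,
                       indication = 0.30, dose = 0.62),
    p_serious = 0.55,
    serious_mix = c(hospitalization = 0.414, death = 0.293,
                    life_threatening = 0.254, disability = 0.023,
                    congenital_anomaly = 0.016),
    p_exceed = c(fluconazole = 0.06, voriconazole = 0.126,
                 itraconazole = 0.6022, posaconazole = 0.4419,
                 isavuconazole = 0.50),
    age_mean = 55.24, age_sd = 15,
    start_date = "2004-01-01", end_date = "2022-09-30",
    pt_cardiac = NULL, pt_other = NULL,
    seed = 1L) {
  map <- fixture_pt_soc()
  if (is.null(pt_cardiac)) {
    pt_cardiac <- map$pt_canon[map$soc == "Cardiac disorders"]
  }
  if (is.null(pt_other)) {
    pt_other <- map$pt_canon[map$soc != "Cardiac disorders"]
  }
  stopifnot(
    n_background_reports >= 0, n_study_reports >= 0,
    all(study_drug_shares >= 0), sum(study_drug_shares) > 0,
    cardiac_share > 0, cardiac_share < 1,
    duplicate_rate >= 0, duplicate_rate < 1,
    all(role_mix >= 0), abs(sum(role_mix) - 1) < 1e-8,
    p_serious >= 0, p_serious <= 1,
    all(unlist(missingness) >= 0), all(unlist(missingness) <= 1),
    all(planted_signals$target_ror > 0),
    all(planted_signals$drug %in% names(study_drug_shares))
  )
  planted_signals$pt <- canon_str(planted_signals$pt)
  if (!all(planted_signals$pt %in% c(pt_cardiac, pt_other))) {
    stop("planted PT(s) outside the event vocabulary", call. = FALSE)
  }
  structure(list(
    n_background_reports = as.integer(n_background_reports),
    n_study_reports = as.integer(n_study_reports),
    study_drug_shares = study_drug_shares / sum(study_drug_shares),
    planted_signals = planted_signals,
    cardiac_share = cardiac_share,
    duplicate_rate = duplicate_rate,
    role_mix = role_mix,
    missingness = missingness,
    p_serious = p_serious,
    serious_mix = serious_mix / sum(serious_mix),
    p_exceed = p_exceed,
    age_mean = age_mean, age_sd = age_sd,
    start_date = as.Date(start_date), end_date = as.Date(end_date),
    pt_cardiac = pt_cardiac, pt_other = pt_other,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# baseline event probabilities: 1/rank decay inside the cardiac and
# non-cardiac blocks, blocks weighted by cardiac_share
base_pt_probs <- function(config) {
  wc <- 1 / seq_along(config$pt_cardiac)
  wo <- 1 / seq_along(config$pt_other)
  p <- c(config$cardiac_share * wc / sum(wc),
         (1 - config$cardiac_share) * wo / sum(wo))
  names(p) <- c(config$pt_cardiac, config$pt_other)
  p
}

# per-drug event probabilities with planted signals: for a planted
# (pt, r) the event probability is raised from the baseline q to
# p = r*q / (1 - q + r*q), which sets the per-report event odds ratio
# (and hence the expected ROR against the unplanted background) to r;
# the remaining PTs are rescaled to keep the distribution normalized
drug_pt_probs <- function(config, drug, base) {
  plant <- config$planted_signals[config$planted_signals$drug == drug, ]
  if (nrow(plant) == 0) return(base)
  p <- base
  q <- base[plant$pt]
  target <- plant$target_ror * q / (1 - q + plant$target_ror * q)
  p[plant$pt] <- target
  rest <- setdiff(names(base), plant$pt)
  p[rest] <- p[rest] * (1 - sum(target)) / (1 - sum(q))
  p
}

render_drug_name <- function(drug, style) {
  brand <- .brand_names[drug]
  strengths <- c("50MG", "100MG", "200MG", "400MG")
  dplyr::case_when(
    style == 1 ~ toupper(drug),
    style == 2 ~ unname(brand),
    .default = paste(unname(brand),
                     strengths[1 + (nchar(drug) %% length(strengths))], "TAB")
  )
}

#' Generate a synthetic FAERS-like database with known ground truth
#'
#' Draws a population of spontaneous reports — background drugs plus the
#' study drugs with planted drug-event association strengths — and renders
#' it as the four quarterly-style tables, together with an exact manifest:
#' true per-stage funnel counts, true contingency cells and realized ROR
#' for every planted signal, and the parameter values used. Duplicates are
#' exact copies of all of a report's records (including the report ID).
#' With a fixed seed the output is byte-identical across runs.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Directory to write `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `OUTC.txt` ("$"-delimited) and `manifest.yaml`. `NULL` keeps
#'   everything in memory.
#' @return (Invisibly when writing) a list with `tables` (raw character
#'   tibbles), `truth` (one row per generated case, duplicates flagged) and
#'   `manifest` (class `faers_manifest`).
#' @export
generate_faers <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_bg <- config$n_background_reports
  n_st <- config$n_study_reports
  n <- n_bg + n_st
  if (n == 0) stop("empty configuration: no reports to generate", call. = FALSE)

  bg_w <- 1 / seq_along(.bg_drugs)
  drug <- c(sample(.bg_drugs, n_bg, replace = TRUE, prob = bg_w / sum(bg_w)),
            sample(names(config$study_drug_shares), n_st, replace = TRUE,
                   prob = config$study_drug_shares))
  is_study <- c(rep(FALSE, n_bg), rep(TRUE, n_st))

  base <- base_pt_probs(config)
  pt <- character(n)
  for (d in unique(drug)) {
    idx <- which(drug == d)
    probs <- if (d %in% config$planted_signals$drug) {
      drug_pt_probs(config, d, base)
    } else base
    pt[idx] <- sample(names(probs), length(idx), replace = TRUE, prob = probs)
  }

  role <- sample(names(config$role_mix), n, replace = TRUE,
                 prob = config$role_mix)
  age <- round(pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                         1), 100), 1)
  age[stats::runif(n) < config$missingness$age] <- NA_real_
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.525, 0.475))
  sex[stats::runif(n) < config$missingness$sex] <- NA_character_
  country <- sample(names(.country_probs), n, replace = TRUE,
                    prob = .country_probs)
  country[stats::runif(n) < config$missingness$country] <- NA_character_
  span <- as.integer(config$end_date - config$start_date)
  receive_date <- config$start_date +
    sample.int(span + 1L, n, replace = TRUE) - 1L

  indication <- ifelse(is_study,
                       sample(.study_indications, n, replace = TRUE),
                       sample(.bg_indications, n, replace = TRUE))
  indication[stats::runif(n) < config$missingness$indication] <- NA_character_

  routine <- routine_dose_map()
  routine_mg <- routine$routine_mg[match(drug, routine$drug)]
  p_exc <- unname(config$p_exceed[drug])
  exceeds <- !is.na(p_exc) & stats::runif(n) < p_exc
  mult <- ifelse(exceeds, sample(c(1.5, 2), n, replace = TRUE),
                 sample(c(0.5, 1), n, replace = TRUE))
  dose <- ifelse(is_study, routine_mg * mult,
                 sample(c(10, 25, 50, 100, 250, 500), n, replace = TRUE))
  dose[stats::runif(n) < config$missingness$dose] <- NA_real_

  serious <- stats::runif(n) < config$p_serious
  outcome <- rep("other", n)
  outcome[serious] <- sample(names(config$serious_mix), sum(serious),
                             replace = TRUE, prob = config$serious_mix)

  style <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  drug_raw <- toupper(drug)
  drug_raw[is_study] <- render_drug_name(drug[is_study], style[is_study])
  pt_raw <- ifelse(stats::runif(n) < 0.5, toupper(pt), pt)

  truth <- tibble::tibble(
    report_id = sprintf("R%07d", seq_len(n)),
    drug = drug, drug_raw = drug_raw, is_study = is_study,
    pt = pt, pt_raw = pt_raw,
    is_cardiac = pt %in% config$pt_cardiac,
    role = role, receive_date = receive_date, age_years = age,
    sex = sex, country = country, indication = indication,
    daily_dose_mg = dose, exceeds_routine = is_study & exceeds,
    outcome = outcome, is_dup_copy = FALSE
  )

  n_dup <- floor(config$duplicate_rate * n)
  if (n_dup > 0) {
    copies <- truth[sample.int(n, n_dup), ]
    copies$is_dup_copy <- TRUE
    truth <- dplyr::bind_rows(truth, copies)
  }

  role_code <- c(primary_suspect = "PS", secondary_suspect = "SS",
                 concomitant = "C", interacting = "I", unknown = "U")
  sex_code <- c(male = "M", female = "F")
  age_is_months <- !is.na(truth$age_years) &
    (as.integer(sub("R", "", truth$report_id)) %% 7L == 0L)

  tables <- list(
    demo = tibble::tibble(
      ISR = truth$report_id,
      RECEIVE_DATE = format(truth$receive_date, "%Y%m%d"),
      AGE = ifelse(is.na(truth$age_years), NA_character_,
                   ifelse(age_is_months,
                          format(truth$age_years * 12, trim = TRUE,
                                 scientific = FALSE),
                          format(truth$age_years, trim = TRUE,
                                 scientific = FALSE))),
      AGE_COD = ifelse(is.na(truth$age_years), NA_character_,
                       ifelse(age_is_months, "MON", "YR")),
      GNDR_COD = unname(sex_code[truth$sex]),
      REPORTER_COUNTRY = truth$country
    ),
    drug = tibble::tibble(
      ISR = truth$report_id,
      DRUGNAME = truth$drug_raw,
      ROLE_COD = unname(role_code[truth$role]),
      INDI_PT = truth$indication,
      DOSE_MG = ifelse(is.na(truth$daily_dose_mg), NA_character_,
                       format(truth$daily_dose_mg, trim = TRUE,
                              scientific = FALSE))
    ),
    reac = tibble::tibble(ISR = truth$report_id, PT = truth$pt_raw),
    outc = tibble::tibble(
      ISR = truth$report_id,
      OUTC_COD = c(death = "DE", life_threatening = "LT",
                   hospitalization = "HO", disability = "DS",
                   congenital_anomaly = "CA", other = "OT")[truth$outcome]
    )
  )

  manifest <- build_manifest(config, truth, tables)

  out <- list(tables = tables, truth = truth, manifest = manifest)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
    fn <- c(demo = "DEMO.txt", drug = "DRUG.txt", reac = "REAC.txt",
            outc = "OUTC.txt")
    for (tab in names(fn)) {
      readr::write_delim(tables[[tab]], file.path(out_dir, fn[[tab]]),
                         delim = "$", na = "", progress = FALSE)
    }
    yaml::write_yaml(manifest_to_list(manifest),
                     file.path(out_dir, "manifest.yaml"))
    return(invisible(out))
  }
  out
}

# exact bookkeeping from the generator's own flags -- independent of the
# pipeline implementation it validates
build_manifest <- function(config, truth, tables) {
  study <- truth[truth$is_study, ]
  cardiac <- study[study$is_cardiac, ]
  base <- truth[!truth$is_dup_copy, ]       # unique reports
  universe <- base[base$role == "primary_suspect", ]

  funnel <- tibble::tibble(
    stage = c("extracted", "soc_restricted", "deduplicated",
              "primary_suspect"),
    n = c(nrow(study), nrow(cardiac),
          sum(!cardiac$is_dup_copy),
          sum(!cardiac$is_dup_copy & cardiac$role == "primary_suspect"))
  )

  planted <- config$planted_signals
  if (nrow(planted)) {
    cells <- lapply(seq_len(nrow(planted)), function(i) {
      d <- planted$drug[i]; p <- planted$pt[i]
      a <- sum(universe$drug == d & universe$pt == p)
      b <- sum(universe$drug == d & universe$pt != p)
      cc <- sum(universe$drug != d & universe$pt == p)
      dd <- sum(universe$drug != d & universe$pt != p)
      tibble::tibble(drug = d, pt = p, target_ror = planted$target_ror[i],
                     a = a, b = b, c = cc, d = dd,
                     realized_ror = (a * dd) / (b * cc))
    })
    planted <- dplyr::bind_rows(cells)
  }

  structure(list(
    seed = config$seed,
    n_reports = sum(!truth$is_dup_copy),
    n_dup_copies = sum(truth$is_dup_copy),
    table_rows = vapply(tables, nrow, integer(1)),
    n_study_rows = nrow(study),
    cardiac_share_study = mean(study$is_cardiac),
    funnel = funnel,
    n_universe = nrow(universe),
    planted = planted
  ), class = "faers_manifest")
}

manifest_to_list <- function(m) {
  list(
    seed = m$seed,
    n_reports = m$n_reports,
    n_dup_copies = m$n_dup_copies,
    table_rows = as.list(m$table_rows),
    n_study_rows = m$n_study_rows,
    cardiac_share_study = m$cardiac_share_study,
    funnel = stats::setNames(as.list(m$funnel$n), m$funnel$stage),
    n_universe = m$n_universe,
    planted = if (nrow(m$planted)) {
      lapply(seq_len(nrow(m$planted)), function(i) as.list(m$planted[i, ]))
    } else list()
  )
}

#' Read a generator manifest back from disk
#'
#' @param path Path to a `manifest.yaml` written by [generate_faers()].
#' @return A `faers_manifest` list (funnel and planted cells as tibbles).
#' @export
read_manifest <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$funnel <- tibble::tibble(stage = names(raw$funnel),
                               n = unlist(raw$funnel, use.names = FALSE))
  raw$planted <- if (length(raw$planted)) {
    dplyr::bind_rows(lapply(raw$planted, tibble::as_tibble))
  } else tibble::tibble()
  raw$table_rows <- unlist(raw$table_rows)
  structure(raw, class = "faers_manifest")
}

#' @export
print.faers_manifest <- function(x, ...) {
  cat(sprintf("<faers_manifest> %d reports (+%d duplicate copies), universe %d\n",
              x$n_reports, x$n_dup_copies, x$n_universe))
  print(x$funnel)
  if (nrow(x$planted)) {
    cat("planted signals:\n")
    print(x$planted)
  }
  invisible(x)
}
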