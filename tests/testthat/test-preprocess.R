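syn <- fixture_synonyms()

test_that("drug names normalize by exact then longest-prefix match", {
  d <- tibble::tibble(drug_name_raw = c("DIFLUCAN", "VFEND 200MG TAB",
                                        "  Sporanox ", "ASPIRIN",
                                        "isavuconazonium sulfate"))
  out <- normalize_drug_names(d, syn)
  expect_equal(out$drug, c("fluconazole", "voriconazole", "itraconazole",
                           "aspirin", "isavuconazole"))
  expect_equal(out$is_study, c(TRUE, TRUE, TRUE, FALSE, TRUE))
})

make_case <- function(pt = "torsade de pointes", report_id = "R1",
                      receive_date = as.Date("2018-01-05"),
                      drug = "fluconazole", indication = "candidiasis",
                      sex = "male", country = "US", age_years = 55,
                      role = "primary_suspect", receive_year = 2018L) {
  tibble::tibble(pt = pt, report_id = report_id,
                 receive_date = receive_date, drug = drug,
                 indication = indication, sex = sex, country = country,
                 age_years = age_years, role = role,
                 receive_year = receive_year)
}

test_that("exact duplicates collapse, near-duplicates survive", {
  two <- dplyr::bind_rows(make_case(), make_case())
  dd <- deduplicate(two)
  expect_equal(nrow(dd), 1)
  expect_equal(attr(dd, "n_removed"), 1)

  # differ only in age (55 vs missing): key mismatch, both survive
  near <- dplyr::bind_rows(make_case(), make_case(age_years = NA))
  expect_equal(nrow(deduplicate(near)), 2)

  # missing == missing: two fully missing-age records still deduplicate
  both_na <- dplyr::bind_rows(make_case(age_years = NA),
                              make_case(age_years = NA))
  expect_equal(nrow(deduplicate(both_na)), 1)
})

test_that("dedup is idempotent and order-independent as a set", {
  cases <- dplyr::bind_rows(
    make_case(), make_case(),
    make_case(report_id = "R2", pt = "rash"),
    make_case(report_id = "R3", age_years = NA))
  once <- deduplicate(cases)
  expect_equal(deduplicate(once), once, ignore_attr = TRUE)

  shuffled <- cases[c(3, 1, 4, 2), ]
  again <- deduplicate(shuffled)
  key <- dedup_key <- c("pt", "report_id", "receive_date", "drug",
                        "indication", "sex", "country", "age_years")
  expect_equal(dplyr::arrange(once[, key], dplyr::pick(dplyr::everything())),
               dplyr::arrange(again[, key], dplyr::pick(dplyr::everything())))
})

test_that("primary-suspect filter keeps exactly the PS rows", {
  roles <- c("primary_suspect", "secondary_suspect", "concomitant",
             "interacting", "unknown")
  cases <- dplyr::bind_rows(lapply(seq_along(roles), function(i)
    make_case(report_id = paste0("R", i), role = roles[i])))
  kept <- filter_primary_suspect(cases)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$role, "primary_suspect")
  expect_equal(nrow(filter_primary_suspect(cases[0, ])), 0)
})

test_that("PS and SOC filters commute", {
  flat <- flatten_bundle(shared_bundle(), syn)
  map <- fixture_pt_soc()
  a <- filter_primary_suspect(filter_cardiac(flat, map))
  b <- filter_cardiac(filter_primary_suspect(flat), map)
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("screening funnel is monotone and matches the manifest exactly", {
  gen <- shared_gen()
  sc <- shared_cases()
  expect_true(all(diff(sc$funnel$n) <= 0))
  expect_equal(sc$funnel$n, gen$manifest$funnel$n)
})

test_that("planted exact-duplicate rate is removed exactly", {
  cfg <- small_config(seed = 99, duplicate_rate = 0.10)
  gen <- generate_faers(cfg)
  b <- bundle_tables(gen$tables)
  sc <- build_cases(b, fixture_pt_soc(), syn)
  removed <- sc$funnel$n[sc$funnel$stage == "soc_restricted"] -
    sc$funnel$n[sc$funnel$stage == "deduplicated"]
  truth <- gen$truth
  expect_equal(removed,
               sum(truth$is_dup_copy & truth$is_study & truth$is_cardiac))
})

test_that("a cardiac event without a study drug contributes no case", {
  tabs <- toy_tables()
  # A9: cardiac PT (torsade) but only a background drug on the report
  tabs$demo <- dplyr::bind_rows(tabs$demo, tibble::tibble(
    ISR = "A9", RECEIVE_DATE = "20150101", AGE = "40", AGE_COD = "YR",
    GNDR_COD = "F", REPORTER_COUNTRY = "US"))
  tabs$drug <- dplyr::bind_rows(tabs$drug, tibble::tibble(
    ISR = "A9", DRUGNAME = "WARFARIN", ROLE_COD = "PS",
    INDI_PT = NA_character_, DOSE_MG = NA_character_))
  tabs$reac <- dplyr::bind_rows(tabs$reac, tibble::tibble(
    ISR = "A9", PT = "Torsade de pointes"))
  paths <- write_quarter_files(tabs)
  sc <- build_cases(read_quarter(paths), fixture_pt_soc(), syn)
  expect_false("A9" %in% sc$cases$report_id)
  # while the fluconazole torsade case (A1, PS role) is retained
  expect_true("A1" %in% sc$cases$report_id)
})
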