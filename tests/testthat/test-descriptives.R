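mini_cases <- function() {
  tibble::tibble(
    report_id = c("R1", "R2", "R3"),
    drug = "fluconazole",
    pt = "torsade de pointes",
    receive_year = c(2018L, 2018L, 2019L),
    receive_date = as.Date(c("2018-01-05", "2018-06-01", "2019-03-03")),
    age_years = c(50, 60, NA),
    sex = c("male", "female", "unknown"),
    country = c("US", "JP", NA),
    daily_dose_mg = c(400, 800, NA),
    outcomes = list(c("death", "hospitalization"), "other", character(0))
  )
}

test_that("sex and age summaries count missing values separately", {
  ch <- summarize_characteristics(mini_cases())
  sex <- ch$sex[ch$sex$drug == "fluconazole", ]
  expect_equal(setNames(sex$n, sex$sex)[c("male", "female", "not_reported")],
               c(male = 1L, female = 1L, not_reported = 1L))
  expect_equal(ch$age$mean_age, 55)
  expect_equal(ch$age$n_not_reported, 1L)
  expect_equal(ch$n_total, 3)
})

test_that("multi-outcome reports get a single category by severity priority", {
  ch <- summarize_characteristics(mini_cases())
  oc <- setNames(ch$outcome$n, ch$outcome$outcome)
  # R1 carries death + hospitalization -> counted once, as death
  expect_equal(oc[["death"]], 1L)
  expect_equal(oc[["hospitalization"]], 0L)
  expect_equal(oc[["other"]], 2L)
  expect_equal(sum(ch$outcome$n), ch$n_total)
})

test_that("serious-outcome share counts any-serious reports over the total", {
  s <- serious_outcome_share(mini_cases())
  flu <- s[s$drug == "fluconazole", ]
  expect_equal(flu$n_serious, 1L)
  expect_equal(flu$share_pct, 33.33)

  all_other <- mini_cases()
  all_other$outcomes <- list("other", "other", character(0))
  expect_equal(serious_outcome_share(all_other)$share_pct, c(0, 0))
})

test_that("yearly counts conserve the total and flag out-of-window years", {
  yc <- yearly_counts(mini_cases())
  expect_equal(sum(yc$total), 3)
  expect_equal(yc$total[yc$year == 2018], 2)
  expect_equal(sum(yc$total_pct), 100, tolerance = 0.02)

  old <- mini_cases()
  old$receive_year[1] <- 1999L
  expect_warning(yc2 <- yearly_counts(old), "outside the study window")
  expect_equal(sum(yc2$total), 2)
})

test_that("doses at or below routine count as not exceeding", {
  da <- dose_analysis(mini_cases())
  # 400 mg equals fluconazole's routine dose -> not exceeding; 800 exceeds
  expect_equal(da$n_known, 2L)
  expect_equal(da$n_at_or_below, 1L)
  expect_equal(da$share_pct, 50)

  none <- mini_cases()
  none$daily_dose_mg <- NA_real_
  expect_true(is.na(dose_analysis(none)$share_pct))

  # share invariant under record order
  rev_da <- dose_analysis(mini_cases()[3:1, ])
  expect_equal(rev_da$share_pct, da$share_pct)
})

test_that("per-drug breakdowns sum to drug totals on synthetic cases", {
  cases <- shared_cases()$cases
  ch <- summarize_characteristics(cases)
  totals <- dplyr::count(dplyr::distinct(cases, .data$report_id, .data$drug),
                         .data$drug)
  for (d in totals$drug) {
    n_d <- totals$n[totals$drug == d]
    expect_equal(sum(ch$sex$n[ch$sex$drug == d]), n_d)
    expect_equal(sum(ch$region$n[ch$region$drug == d]), n_d)
    expect_equal(sum(ch$outcome$n[ch$outcome$drug == d]), n_d)
    age_d <- ch$age[ch$age$drug == d, ]
    expect_equal(age_d$n_reported + age_d$n_not_reported, n_d)
  }
  # the generated cohort is drawn around the configured mean age; check on
  # the full demographics table where the sampling error is small
  demo_mean <- mean(shared_bundle()$demographics$age_years, na.rm = TRUE)
  expect_lt(abs(demo_mean - 55.24), 1.0)

  s <- serious_outcome_share(cases)
  tot <- s[s$drug == "Total", ]
  expect_equal(sum(s$n_reports[s$drug != "Total"]), tot$n_reports)
})

test_that("distribution shares reproduce simple ratio arithmetic", {
  counts <- tibble::tibble(drug = c("x", "y"),
                           taa_ae_n = c(300L, 700L),
                           cardiac_ae_n = c(30L, 70L),
                           ps_n = c(10L, 30L))
  d <- summarize_distribution(counts)
  expect_equal(d$cardiac_share_of_taa, 10)
  expect_equal(d$ps_share_of_cardiac, 40)
  expect_equal(d$table$taa_ae_pct, c(30, 70))
})

test_that("percentages round half away from zero", {
  expect_equal(round_half_up(42.385), 42.39)
  expect_equal(round_half_up(8.025), 8.03)
  expect_equal(round_half_up(-1.25, 1), -1.3)
  expect_equal(pct(1, 3), 33.33)
  expect_true(is.na(pct(0, 0)))
})
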