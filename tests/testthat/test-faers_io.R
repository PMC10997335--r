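test_that("a minimal demographics table loads with correct parsing", {
  paths <- write_quarter_files(toy_tables())
  b <- read_quarter(paths)

  expect_s3_class(b, "faers_bundle")
  expect_equal(nrow(b$demographics), 3)
  expect_equal(nrow(b$quarantine), 0)
  # months converted to years, unit-free age taken as years
  expect_equal(b$demographics$age_years, c(55, 60, NA))
  expect_equal(b$demographics$sex, c("male", "female", "unknown"))
  expect_equal(b$demographics$receive_date[1], as.Date("2018-01-05"))
  # PTs and drug names case-folded at load
  expect_equal(b$reactions$pt[1], "torsade de pointes")
  expect_equal(b$drugs$drug_name_raw[1], "diflucan")
})

test_that("unrecognized role codes map to unknown and are retained", {
  paths <- write_quarter_files(toy_tables())
  b <- read_quarter(paths)
  expect_equal(b$drugs$role,
               c("primary_suspect", "concomitant", "secondary_suspect",
                 "unknown"))
  expect_equal(nrow(b$drugs), 4)  # the XX-coded row is kept, not dropped
})

test_that("malformed rows are quarantined, never silently dropped", {
  tabs <- toy_tables()
  tabs$demo <- dplyr::bind_rows(tabs$demo, tibble::tibble(
    ISR = c("B1", "B2", "B3", ""),
    RECEIVE_DATE = c("not-a-date", "20250101", "19850101", "20200101"),
    AGE = c("50", "-3", "abc", NA),
    AGE_COD = c("YR", "YR", "YR", NA),
    GNDR_COD = "M", REPORTER_COUNTRY = "US"))
  tabs$drug <- dplyr::bind_rows(tabs$drug, tibble::tibble(
    ISR = "ZZ9", DRUGNAME = "ASPIRIN", ROLE_COD = "C",
    INDI_PT = NA_character_, DOSE_MG = "-10"))
  paths <- write_quarter_files(tabs)
  b <- read_quarter(paths)

  # B1 fails on its date, B2 on its negative age, B3 on a pre-1990 date,
  # the blank-ISR row on the missing key
  q <- b$quarantine
  expect_true("unparseable receive_date" %in% q$reason)
  expect_true(any(grepl("age", q$reason)))
  expect_true("missing report_id" %in% q$reason)
  # orphan drug record (ZZ9 has no demographics row) quarantined, and the
  # non-positive dose row never reaches the accepted set
  expect_true(any(q$reason == "non-positive dose" | q$reason == "orphan report_id"))

  # conservation: accepted + quarantined = input, per table
  expect_equal(b$counts$n_accepted + b$counts$n_quarantined,
               b$counts$n_input)
})

test_that("missing files and unknown layouts are fatal with context", {
  paths <- write_quarter_files(toy_tables())
  bad <- paths
  bad[["reac"]] <- file.path(dirname(paths[["reac"]]), "nope.txt")
  expect_error(read_quarter(bad), "reac")

  tabs <- toy_tables()
  names(tabs$reac) <- c("WHO_KNOWS", "WHAT_THIS_IS")
  paths2 <- write_quarter_files(tabs)
  expect_error(read_quarter(paths2), "unknown column layout")
})

test_that("written tables round-trip without loss", {
  dir <- withr::local_tempdir()
  # empty table -> header only
  empty <- tibble::tibble(drug = character(), n = integer())
  p <- write_table(empty, file.path(dir, "empty.tsv"))
  expect_equal(length(readLines(p)), 1)

  tbl <- tibble::tibble(drug = c("fluconazole", "itraconazole", "aspirin"),
                        a = c(40L, 3L, 0L), b = c(960L, 17L, 5L),
                        ror = c(10.114583, 417.37, NA))
  p2 <- write_table(tbl, file.path(dir, "ct.tsv"))
  expect_equal(length(readLines(p2)), 4)  # header + 3 rows
  back <- readr::read_tsv(p2, col_types = "ciid")
  expect_equal(as.data.frame(back), as.data.frame(tbl))
})

test_that("loader table counts match the generator manifest", {
  gen <- shared_gen()
  b <- shared_bundle()
  expect_equal(setNames(b$counts$n_input, b$counts$table),
               gen$manifest$table_rows)
  expect_equal(sum(b$counts$n_quarantined), 0)
})
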