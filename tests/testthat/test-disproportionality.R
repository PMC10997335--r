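tbl4 <- function(a, b, c, d) tibble::tibble(a = a, b = b, c = c, d = d)

test_that("contingency cells are exact on a toy universe", {
  u <- tibble::tibble(report_id = as.character(1:4),
                      drug = c("d", "d", "f", "f"),
                      pt = c("e", "x", "e", "x"))
  ct <- build_contingency(u, "d", "e")
  expect_equal(unlist(ct[, c("a", "b", "c", "d")]),
               c(a = 1L, b = 1L, c = 1L, d = 1L))

  # event never seen with the drug: a = 0, b = the drug's total
  ct0 <- build_contingency(u, "d", "never seen")
  expect_equal(ct0$a, 0L)
  expect_equal(ct0$b, 2L)
  # absent drug is not an error
  expect_equal(build_contingency(u, "ghost", "e")$a, 0L)
})

test_that("swapping drug and event roles transposes the table", {
  set.seed(5)
  for (i in 1:10) {
    n <- 60
    u <- tibble::tibble(report_id = as.character(seq_len(n)),
                        drug = sample(c("d", "f", "g"), n, TRUE),
                        pt = sample(c("e", "x", "y"), n, TRUE))
    ct <- build_contingency(u, "d", "e")
    swapped <- build_contingency(
      tibble::tibble(report_id = u$report_id, drug = u$pt, pt = u$drug),
      "e", "d")
    expect_equal(swapped$a, ct$a)
    expect_equal(swapped$b, ct$c)
    expect_equal(swapped$c, ct$b)
    expect_equal(swapped$d, ct$d)
  }
})

test_that("ROR point estimate and CI match the closed form", {
  r <- ror(tbl4(10, 90, 100, 9900))
  expect_equal(r$ror, 11.0)
  # frozen from exp(log(11) -/+ 1.96 * sqrt(1/10 + 1/90 + 1/100 + 1/9900))
  expect_equal(r$ror_low, 5.55951493, tolerance = 1e-7)
  expect_equal(r$ror_high, 21.76448873, tolerance = 1e-7)
  expect_equal(round_half_up(c(r$ror_low, r$ror_high)), c(5.56, 21.76))

  # symmetric table: ROR and PRR both 1 for any k
  for (k in c(1, 7, 50)) {
    expect_equal(ror(tbl4(k, k, k, k))$ror, 1.0)
    expect_equal(prr(tbl4(k, k, k, k))$prr, 1.0)
  }
})

test_that("PRR matches the proportion-ratio form", {
  p <- prr(tbl4(10, 90, 100, 9900))
  expect_equal(p$prr, 10.0)
  expect_true(p$prr_low < 10 && p$prr_high > 10)
})

test_that("zero-cell behavior: ROR undefined where PRR is still computable", {
  # c = 0: ROR cannot be computed; PRR is infinite and flagged
  r <- ror(tbl4(5, 95, 0, 1000))
  expect_false(r$ror_defined)
  expect_equal(r$ror_reason, "zero-cell b or c")
  p <- prr(tbl4(5, 95, 0, 1000))
  expect_true(p$prr_defined)
  expect_equal(p$prr, Inf)
  expect_equal(p$prr_reason, "zero c: infinite")
  expect_true(is.na(p$prr_low))

  # b = 0 kills the ROR too; a = 0 kills both
  expect_false(ror(tbl4(5, 0, 10, 1000))$ror_defined)
  expect_false(ror(tbl4(0, 100, 10, 1000))$ror_defined)
  expect_false(prr(tbl4(0, 100, 10, 1000))$prr_defined)

  # Haldane continuity correction rescues the estimate when asked
  rh <- ror(tbl4(5, 95, 0, 1000), haldane = TRUE)
  expect_true(rh$ror_defined)
  expect_true(is.finite(rh$ror))
})

test_that("both statistics increase strictly in a", {
  a <- 1:30
  r <- ror(tbl4(a, 100, 50, 5000))
  p <- prr(tbl4(a, 100, 50, 5000))
  expect_true(all(diff(r$ror) > 0))
  expect_true(all(diff(p$prr) > 0))
})

test_that("dual criteria gate on count, ROR lower bound, PRR and chi-squared", {
  res <- tibble::tibble(
    n = c(3, 2, 3, 3, 3),
    ror_low = c(1.2, 1.2, 0.99, 1.2, NA),
    prr = c(2.5, 2.5, 2.5, 1.9, 2.5),
    chi2_yates = c(5, 5, 5, 5, 5))
  out <- apply_criteria(res)
  expect_equal(out$is_signal, c(TRUE, FALSE, FALSE, FALSE, FALSE))

  # chi-squared below threshold blocks the PRR criterion
  low_chi <- apply_criteria(tibble::tibble(n = 3, ror_low = 1.2, prr = 2.5,
                                           chi2_yates = 3.9))
  expect_false(low_chi$is_signal)
  # ... unless the gate is disabled (replaying printed tables)
  no_chi <- apply_criteria(tibble::tibble(n = 3, ror_low = 1.2, prr = 2.5),
                           signal_criteria(use_chi2 = FALSE))
  expect_true(no_chi$is_signal)
})

test_that("planted contingency cells are recovered exactly from the manifest", {
  gen <- shared_gen()
  u <- shared_universe()
  m <- gen$manifest$planted
  ct <- build_contingency(u, m$drug[1], m$pt[1])
  expect_equal(unlist(ct[, c("a", "b", "c", "d")]),
               unlist(m[1, c("a", "b", "c", "d")]))
})

test_that("the vectorized signal grid agrees with per-pair contingency tables", {
  u <- shared_universe()
  st <- signal_table(u, map = fixture_pt_soc())
  expect_true(nrow(st) > 0)
  for (i in sample(nrow(st), min(5, nrow(st)))) {
    ct <- build_contingency(u, st$drug[i], st$pt[i])
    expect_equal(unlist(st[i, c("a", "b", "c", "d")]),
                 unlist(ct[, c("a", "b", "c", "d")]))
  }
  # table invariant: a+b+c+d = universe total, per row
  n_pairs <- nrow(dplyr::distinct(u[, c("report_id", "drug")]))
  expect_true(all(st$a + st$b + st$c + st$d == n_pairs))
  # sorted per drug by descending ROR
  for (d in unique(st$drug)) {
    expect_false(is.unsorted(rev(st$ror[st$drug == d]), na.rm = TRUE))
  }
})

test_that("the planted association is flagged as a signal", {
  st <- signal_table(shared_universe(), map = fixture_pt_soc())
  planted <- st[st$drug == "fluconazole" & st$pt == "torsade de pointes", ]
  expect_equal(nrow(planted), 1)
  expect_true(planted$is_signal)
  expect_gt(planted$ror, 5)
})
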