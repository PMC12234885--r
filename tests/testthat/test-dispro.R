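test_that("hand-computed point estimates are reproduced", {
  expect_equal(compute_ror(5, 5, 5, 5)$ror, 1)
  r <- compute_ror(5, 5, 5, 5)
  expect_true(r$ror_low < 1 && r$ror_high > 1)
  expect_equal(compute_ror(10, 90, 100, 9900)$ror, 11)
  expect_equal(compute_prr_chi2(10, 90, 100, 9900)$prr, 10)
  expect_equal(compute_prr_chi2(25, 25, 25, 25)$prr, 1)
  expect_equal(compute_prr_chi2(25, 25, 25, 25)$chi2, 0)
  expect_equal(round_half_up(compute_ebgm(10, 90, 100, 9900)$ebgm, 2), 9.18)
})

test_that("IC is exactly log2 of the unshrunk EBGM", {
  withr::local_seed(42)
  for (i in 1:50) {
    t <- random_table()
    ic <- compute_ic(t$a, t$b, t$c, t$d)$ic
    ebgm <- compute_ebgm(t$a, t$b, t$c, t$d)$ebgm
    expect_equal(ic, log2(ebgm), tolerance = 1e-12)
  }
})

test_that("analytically independent tables give unit statistics exactly", {
  tabs <- list(c(3, 7, 30, 70), c(5, 5, 50, 50), c(12, 28, 3, 7))
  for (t in tabs) {
    expect_equal(compute_ror(t[1], t[2], t[3], t[4])$ror, 1)
    pc <- compute_prr_chi2(t[1], t[2], t[3], t[4])
    expect_equal(pc$prr, 1)
    expect_equal(pc$chi2, 0)
    expect_equal(compute_ic(t[1], t[2], t[3], t[4])$ic, 0)
    expect_equal(compute_ebgm(t[1], t[2], t[3], t[4])$ebgm, 1)
  }
})

test_that("ROR bounds PRR away from 1 whenever cells are positive", {
  withr::local_seed(99)
  checked <- 0
  while (checked < 50) {
    t <- random_table()
    ror <- compute_ror(t$a, t$b, t$c, t$d)$ror
    prr <- compute_prr_chi2(t$a, t$b, t$c, t$d)$prr
    if (abs(ror - 1) < 1e-9) next
    if (ror > 1) expect_true(ror > prr && prr > 1)
    if (ror < 1) expect_true(ror < prr && prr < 1)
    checked <- checked + 1
  }
})

test_that("chi-square is invariant under transposition of the table", {
  withr::local_seed(7)
  for (i in 1:25) {
    t <- random_table()
    expect_equal(compute_prr_chi2(t$a, t$b, t$c, t$d)$chi2,
                 compute_prr_chi2(t$a, t$c, t$b, t$d)$chi2,
                 tolerance = 1e-12)
  }
})

test_that("chi-square equals the textbook expected-count form", {
  withr::local_seed(123)
  for (i in 1:200) {
    t <- random_table()
    expect_equal(compute_prr_chi2(t$a, t$b, t$c, t$d)$chi2,
                 chi2_oracle(t$a, t$b, t$c, t$d), tolerance = 1e-9)
  }
})

test_that("zero cells raise a typed error unless the Haldane correction is on", {
  expect_error(compute_ror(0, 10, 10, 100), "'a'",
               class = "faersignal_undefined_statistic")
  expect_error(compute_ror(5, 10, 0, 100), "'c'",
               class = "faersignal_undefined_statistic")
  expect_error(compute_ebgm(5, 0, 10, 100),
               class = "faersignal_undefined_statistic")
  r <- compute_ror(5, 10, 0, 100, correction = TRUE)
  expect_true(is.finite(r$ror) && r$corrected)
  # untouched tables are not corrected
  r2 <- compute_ror(5, 10, 2, 100, correction = TRUE)
  expect_false(r2$corrected)
  expect_equal(r2$ror, compute_ror(5, 10, 2, 100)$ror)
})

test_that("the Bate posterior interval is available and sane", {
  delta <- compute_ic(20, 80, 100, 9800)
  bate <- compute_ic(20, 80, 100, 9800, variance = "bate")
  expect_equal(delta$ic, bate$ic)  # the point estimate is the printed IC
  expect_true(bate$ic025 < bate$ic975)
  # at large counts the posterior mean approaches the raw IC
  big <- compute_ic(2000, 8000, 10000, 980000, variance = "bate")
  expect_lt(abs((big$ic025 + big$ic975) / 2 - big$ic), 0.05)
})

test_that("signal flags implement the threshold rules and their gates", {
  thr <- signal_thresholds()
  # a = 2 with an enormous ROR is still gated out
  s <- disproportionality(tibble::tibble(pt_name = "X", soc_name = NA,
                                         soc_code = NA, a = 2L, b = 8L,
                                         c = 1L, d = 989L), thr)
  expect_false(s$ror_pos)
  expect_false(s$prr_pos)
  # an independence table trips nothing
  s0 <- disproportionality(tibble::tibble(pt_name = "X", soc_name = NA,
                                          soc_code = NA, a = 25L, b = 25L,
                                          c = 25L, d = 25L), thr)
  expect_false(s0$any_pos)
  # a strong table trips everything
  s1 <- disproportionality(tibble::tibble(pt_name = "X", soc_name = NA,
                                          soc_code = NA, a = 131L,
                                          b = 7387L, c = 8510L,
                                          d = 41068431L), thr)
  expect_true(s1$all_pos)
  expect_true(s1$any_pos)
})

test_that("margin reconstruction is self-consistent and inverts the pipeline", {
  # published-row inversion: recomputing PRR and EBGM from the
  # reconstructed table returns the inputs within 0.5%
  t <- reconstruct_margins(a = 131, ab = 7518, prr = 84.11, ebgm = 82.85)
  expect_gt(t$c, 8000); expect_lt(t$c, 9000)
  expect_gt(t$n_total, 4e7); expect_lt(t$n_total, 4.2e7)
  prr_back <- compute_prr_chi2(t$a, t$b, t$c, t$d)$prr
  ebgm_back <- compute_ebgm(t$a, t$b, t$c, t$d)$ebgm
  expect_lt(abs(prr_back / 84.11 - 1), 0.005)
  expect_lt(abs(ebgm_back / 82.85 - 1), 0.005)

  # null inversion recovers the balanced independence table
  t0 <- reconstruct_margins(a = 3, ab = 6, prr = 1, ebgm = 1)
  expect_equal(unlist(t0[c("a", "b", "c", "d")]), c(a = 3, b = 3, c = 3, d = 3))

  # forward-inverse round trip on arbitrary tables, within integer rounding
  withr::local_seed(31)
  for (i in 1:20) {
    a <- sample(3:50, 1); b <- sample(50:500, 1)
    cc <- sample(10:200, 1); d <- sample(1000:50000, 1)
    prr <- compute_prr_chi2(a, b, cc, d)$prr
    ebgm <- compute_ebgm(a, b, cc, d)$ebgm
    if (abs(prr - ebgm) < 1e-6) next
    back <- reconstruct_margins(a, a + b, prr, ebgm)
    expect_lte(abs(back$c - cc), 1)
    expect_lte(abs(back$n_total - (a + b + cc + d)), 1)
  }

  # equal-but-not-unit PRR/EBGM cannot be inverted (the printed pallor row
  # rounds to this degenerate corner)
  expect_error(reconstruct_margins(12, 7518, 3.79, 3.79),
               class = "faersignal_infeasible")
  expect_error(reconstruct_margins(10, 100, 0.5, 2),
               class = "faersignal_infeasible")
})
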