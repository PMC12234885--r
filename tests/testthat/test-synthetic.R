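test_that("the same configuration and seed yield byte-identical files", {
  cfg <- synthetic_config(n_cases = 300, n_drugs = 6, n_events = 15,
                          seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_faers(cfg, dir = d1)
  generate_faers(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), info = f)
  }
  # a different seed produces different data
  d3 <- withr::local_tempdir()
  generate_faers(synthetic_config(n_cases = 300, n_drugs = 6,
                                  n_events = 15, seed = 8), dir = d3)
  expect_false(identical(readLines(file.path(d1, "reac.txt")),
                         readLines(file.path(d3, "reac.txt"))))
})

test_that("no duplication means one report per case", {
  cfg <- synthetic_config(n_cases = 500, n_drugs = 6, n_events = 15,
                          duplication_rate = 0, seed = 3)
  g <- generate_faers(cfg)
  expect_equal(nrow(g$quarter$demo), 500L)
  expect_equal(g$truth$n_reports, 500L)
})

test_that("deduplicated case counts equal the generator's ground truth", {
  for (rate in c(0, 0.2, 0.5)) {
    cfg <- synthetic_config(n_cases = 500, n_drugs = 6, n_events = 15,
                            duplication_rate = rate, deletion_rate = 0.02,
                            seed = 17)
    g <- generate_faers(cfg)
    cases <- suppressMessages(deduplicate(g$quarter))
    expect_equal(n_cases(cases), g$truth$n_unique,
                 info = paste("duplication_rate", rate))
  }
})

test_that("a planted tenfold association is empirically near tenfold", {
  # a moderately rare PT, where the per-drug renormalization and the
  # multiple-mentions saturation (both documented deflators of the realized
  # case-level ratio) stay small
  cfg <- synthetic_config(
    n_cases = 20000, seed = 41,
    planted_pairs = data.frame(drug = "HEMANGEOL", event = "EVT051",
                               rr = 10)
  )
  # the model-implied case-level rate ratio itself is within 25% of 10
  e <- expected_contingency(cfg, event = "EVT051")
  rr_model <- (e$a / (e$a + e$b)) / (e$c / (e$c + e$d))
  expect_gt(rr_model, 7.5)
  expect_lt(rr_model, 12.5)
  # and so is the empirical ratio, pooling three replicates of 20,000 cases
  counts <- c(a = 0, cohort = 0, c = 0, bg = 0)
  for (s in 41:43) {
    cfg$seed <- s
    g <- generate_faers(cfg)
    ec <- g$truth$event_counts
    row <- ec[ec$pt_name == "EVT051", ]
    counts <- counts + c(row$a_true, g$truth$n_cohort, row$c_true,
                         g$truth$n_unique - g$truth$n_cohort)
  }
  rr_hat <- (counts["a"] / counts["cohort"]) / (counts["c"] / counts["bg"])
  expect_gt(rr_hat, 7.5)
  expect_lt(rr_hat, 12.5)
})

test_that("closed-form expected cells match a Monte-Carlo average within 3 SE", {
  cfg <- synthetic_config(
    n_cases = 400, n_drugs = 6, n_events = 20, n_target = 80,
    ps_fraction = 1, duplication_rate = 0, deletion_rate = 0,
    events_per_case_lambda = 2, seed = 1,
    planted_pairs = data.frame(drug = "HEMANGEOL", event = "EVT005",
                               rr = 5)
  )
  exp_cells <- expected_contingency(cfg, event = "EVT005")
  sims <- vapply(1:200, function(s) {
    cfg_s <- cfg
    cfg_s$seed <- s
    g <- generate_faers(cfg_s)
    ec <- g$truth$event_counts
    row <- ec[ec$pt_name == "EVT005", ]
    c(a = if (nrow(row)) row$a_true else 0L,
      c = if (nrow(row)) row$c_true else 0L)
  }, numeric(2))
  for (cell in c("a", "c")) {
    m <- mean(sims[cell, ])
    se <- stats::sd(sims[cell, ]) / sqrt(ncol(sims))
    expect_lt(abs(m - exp_cells[[cell]]), 3 * se,
              label = sprintf("cell %s: mean %.2f vs expected %.2f", cell,
                              m, exp_cells[[cell]]))
  }
})

test_that("without planting the expected cells are exactly null", {
  cfg <- synthetic_config(n_cases = 1000, n_drugs = 10, n_events = 30,
                          seed = 1)
  e <- expected_contingency(cfg, event = "EVT003")
  ror <- (e$a * e$d) / (e$b * e$c)
  expect_equal(ror, 1, tolerance = 1e-12)
})

test_that("planted expectations exceed all four thresholds at study scale", {
  cfg <- synthetic_config(
    n_cases = 20000, seed = 1,
    planted_pairs = data.frame(drug = "HEMANGEOL", event = "EVT011",
                               rr = 10)
  )
  e <- expected_contingency(cfg, event = "EVT011")
  expect_gte(e$a, 30)
  s <- disproportionality(
    tibble::tibble(pt_name = "EVT011", soc_name = NA, soc_code = NA,
                   a = round(e$a), b = round(e$b), c = round(e$c),
                   d = round(e$d))
  )
  expect_true(s$all_pos)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_cases = 100, n_events = 10,
                                background_event_probs = rep(1, 10)),
               class = "faersignal_config_error")
  expect_error(synthetic_config(planted_pairs = data.frame(
    drug = "X", event = "EVT001", rr = -1)))
  cfg <- synthetic_config(n_cases = 50, n_drugs = 4, n_events = 10,
                          planted_pairs = data.frame(
                            drug = "HEMANGEOL", event = "NOSUCH", rr = 2),
                          seed = 2)
  expect_error(generate_faers(cfg), class = "faersignal_config_error")
  expect_error(expected_contingency(cfg, event = "NOSUCH"),
               class = "faersignal_lookup_error")
})
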