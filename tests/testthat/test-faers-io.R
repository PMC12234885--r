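test_that("a fixture quarter round-trips with zero dropped rows", {
  dir <- withr::local_tempdir()
  fixture_quarter(dir)
  q <- read_quarter(dir)
  expect_s3_class(q, "faers_quarter")
  expect_equal(nrow(q$demo), 3L)
  expect_equal(sum(q$load_report$rows_dropped), 0L)
  expect_setequal(q$load_report$table,
                  c("demo", "drug", "reac", "outc", "rpsr", "ther", "indi"))
})

test_that("rows with a non-numeric primaryid are dropped and counted", {
  dir <- withr::local_tempdir()
  fixture_quarter(dir)
  cat("BADID$HEADACHE\n", file = file.path(dir, "reac.txt"), append = TRUE)
  q <- read_quarter(dir)
  expect_equal(q$load_report$rows_dropped[q$load_report$table == "reac"], 1L)
  expect_equal(nrow(q$reac), 4L)
})

test_that("format errors name the table and column; empty DEMO is fatal", {
  dir <- withr::local_tempdir()
  fixture_quarter(dir)
  reac <- readr::read_delim(file.path(dir, "reac.txt"), delim = "$",
                            show_col_types = FALSE)
  write_table(dplyr::rename(reac, pt = pt_name), dir, "reac.txt")
  expect_error(read_quarter(dir), "REAC.*pt_name",
               class = "faersignal_format_error")
  fixture_quarter(dir)
  writeLines(paste(names(demo_row(1, 1)), collapse = "$"),
             file.path(dir, "demo.txt"))
  expect_error(read_quarter(dir), "DEMO",
               class = "faersignal_format_error")
})

test_that("generated quarters are identical after a write-read round trip", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_cases = 1000, n_drugs = 10, n_events = 30,
                          seed = 11)
  g <- generate_faers(cfg, dir = dir)
  q <- read_quarter(dir)
  for (tb in c("demo", "drug", "reac", "outc", "rpsr", "ther", "indi")) {
    expect_equal(as.data.frame(q[[tb]]), as.data.frame(g$quarter[[tb]]),
                 info = tb)
  }
  expect_equal(q$deleted, g$quarter$deleted)
  expect_equal(sum(q$load_report$rows_dropped), 0L)
})

test_that("deduplication keeps the latest submission and honours the deleted list", {
  dir <- withr::local_tempdir()
  dedup_quarter(dir)
  cases <- suppressMessages(deduplicate(read_quarter(dir)))
  # caseid 101: only the 2021-03-02 version survives
  expect_equal(cases$cases$primaryid[cases$cases$caseid == "101"], "1012")
  # caseid 102 was deleted
  expect_false("102" %in% cases$cases$caseid)
  # caseid 104: tied dates, larger primaryid wins (and the tie is messaged)
  expect_message(deduplicate(read_quarter(dir)), "tied submission dates")
  expect_equal(cases$cases$primaryid[cases$cases$caseid == "104"], "1042")
  expect_equal(sort(cases$cases$caseid), c("101", "103", "104"))
})

test_that("deduplication is idempotent and loses only deleted caseids", {
  cfg <- synthetic_config(n_cases = 400, n_drugs = 8, n_events = 20,
                          duplication_rate = 0.3, deletion_rate = 0.05,
                          seed = 5)
  g <- generate_faers(cfg)
  cases1 <- suppressMessages(deduplicate(g$quarter))
  # output caseids = input caseids minus the deleted list, as sets
  expect_setequal(cases1$cases$caseid,
                  setdiff(unique(g$quarter$demo$caseid), g$quarter$deleted))
  # re-wrap the surviving reports as a quarter; a second pass is a no-op
  q2 <- g$quarter
  keep <- cases1$cases$primaryid
  for (tb in c("demo", "drug", "reac", "outc", "rpsr", "ther", "indi")) {
    q2[[tb]] <- q2[[tb]][q2[[tb]]$primaryid %in% keep, ]
  }
  q2$deleted <- character()
  cases2 <- suppressMessages(deduplicate(q2))
  for (part in c("cases", "drugs", "reactions", "outcomes")) {
    expect_equal(
      as.data.frame(dplyr::arrange(cases2[[part]],
                                   dplyr::across(dplyr::everything()))),
      as.data.frame(dplyr::arrange(cases1[[part]],
                                   dplyr::across(dplyr::everything()))),
      info = part
    )
  }
  # case count never exceeds report count
  expect_lte(n_cases(cases1), nrow(g$quarter$demo))
})

test_that("report-level counting keeps every version as its own unit", {
  cfg <- synthetic_config(n_cases = 300, n_drugs = 6, n_events = 15,
                          duplication_rate = 0.4, deletion_rate = 0,
                          seed = 9)
  g <- generate_faers(cfg)
  by_case <- suppressMessages(deduplicate(g$quarter, counting = "case"))
  by_report <- suppressMessages(deduplicate(g$quarter, counting = "report"))
  expect_equal(n_cases(by_case), 300L)
  expect_equal(n_cases(by_report), nrow(g$quarter$demo))
  expect_gt(n_cases(by_report), n_cases(by_case))
})

test_that("ages convert by unit and missingness propagates", {
  expect_equal(normalize_age(6, "MON"), 0.5)
  expect_equal(normalize_age(2, "DEC"), 20)
  expect_equal(normalize_age(26, "WK"), 0.5)
  expect_equal(normalize_age(365.25, "DY"), 1)
  expect_equal(normalize_age(8766, "HR"), 1)
  expect_true(is.na(normalize_age(NA, "YR")))
  expect_true(is.na(normalize_age(5, "")))
  expect_warning(res <- normalize_age(-2, "YR"), "negative")
  expect_true(is.na(res))
})

test_that("truncated dates order deduplication but never feed onset", {
  p <- parse_faers_date(c("20200115", "202001", "2020", "garbage", ""))
  expect_equal(p$exact, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(p$date[1:3],
               as.Date(c("2020-01-15", "2020-01-01", "2020-01-01")))
  expect_true(all(is.na(p$date[4:5])))

  # an exact event date yields onset; a month-resolution one does not
  dir <- withr::local_tempdir()
  fixture_quarter(dir)
  demo <- dplyr::bind_rows(
    demo_row(1011, 101, event_date = "20200301"),
    demo_row(1021, 102, event_date = "202003")
  )
  write_table(demo, dir, "demo.txt")
  write_table(tibble::tibble(primaryid = c("1011", "1021"), drug_seq = "1",
                             role_code = "PS", drugname = "HEMANGEOL",
                             prod_ai = "X"), dir, "drug.txt")
  write_table(tibble::tibble(primaryid = c("1011", "1021"),
                             pt_name = "PYREXIA"), dir, "reac.txt")
  stub_tables(dir, c("1011", "1021"))
  cases <- deduplicate(read_quarter(dir))
  expect_equal(cases$cases$onset_days[cases$cases$caseid == "101"], 60L)
  expect_true(is.na(cases$cases$onset_days[cases$cases$caseid == "102"]))
})
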