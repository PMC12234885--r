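# Fixtures are built in code: tiny dollar-delimited quarters written to a
# temp dir, plus a direct constructor for case sets with known strata.

write_table <- function(df, dir, name) {
  readr::write_delim(df, file.path(dir, name), delim = "$", na = "")
}

# minimal valid rows for the ancillary tables
stub_tables <- function(dir, primaryids) {
  write_table(tibble::tibble(primaryid = primaryids, rpsr_code = "HP"),
              dir, "rpsr.txt")
  write_table(tibble::tibble(primaryid = primaryids, drug_seq = "1",
                             therapy_start_date = "20200101"),
              dir, "ther.txt")
  write_table(tibble::tibble(primaryid = primaryids, drug_seq = "1",
                             indication_pt = "INFANTILE HAEMANGIOMA"),
              dir, "indi.txt")
}

demo_row <- function(primaryid, caseid, version = "1",
                     submission = "20200115", age_value = "6",
                     age_unit = "MON", sex = "F", weight = "5.0",
                     reporter = "MD", country = "US", event_date = "") {
  tibble::tibble(
    primaryid = as.character(primaryid), caseid = as.character(caseid),
    case_version = version, submission_date = submission,
    age_value = age_value, age_unit = age_unit, sex = sex,
    weight_kg = weight, reporter_type = reporter,
    reporter_country = country, event_date = event_date
  )
}

# three single-version cases: 101 has the target drug as PS, 102 carries it
# only as concomitant, 103 is unrelated
fixture_quarter <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  demo <- dplyr::bind_rows(
    demo_row(1011, 101),
    demo_row(1021, 102, sex = "M"),
    demo_row(1031, 103, sex = "")
  )
  drug <- tibble::tibble(
    primaryid = c("1011", "1021", "1021", "1031"),
    drug_seq = c("1", "1", "2", "1"),
    role_code = c("PS", "PS", "C", "PS"),
    drugname = c("Hemangeol Oral Solution", "OTHERDRUG", "HEMANGEOL",
                 "DRUGX"),
    prod_ai = c("PROPRANOLOL HYDROCHLORIDE", "OTHERDRUG",
                "PROPRANOLOL HYDROCHLORIDE", "DRUGX")
  )
  reac <- tibble::tibble(
    primaryid = c("1011", "1011", "1021", "1031"),
    pt_name = c("PERIPHERAL COLDNESS", "CYANOSIS", "ILLNESS", "RASH")
  )
  outc <- tibble::tibble(primaryid = c("1011", "1021"),
                         outcome_code = c("HO", "OT"))
  write_table(demo, dir, "demo.txt")
  write_table(drug, dir, "drug.txt")
  write_table(reac, dir, "reac.txt")
  write_table(outc, dir, "outc.txt")
  stub_tables(dir, demo$primaryid)
  writeLines(character(), file.path(dir, "deleted.txt"))
  dir
}

# versioned and deleted cases: 101 has two versions, 102 is deleted, 104 has
# a tied submission date across two primaryids
dedup_quarter <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  demo <- dplyr::bind_rows(
    demo_row(1011, 101, "1", "20200115"),
    demo_row(1012, 101, "2", "20210302"),
    demo_row(1021, 102, "1", "20200601"),
    demo_row(1031, 103, "1", "20200801"),
    demo_row(1041, 104, "1", "20220505"),
    demo_row(1042, 104, "2", "20220505")
  )
  drug <- tibble::tibble(
    primaryid = demo$primaryid, drug_seq = "1", role_code = "PS",
    drugname = "HEMANGEOL", prod_ai = "PROPRANOLOL HYDROCHLORIDE"
  )
  reac <- tibble::tibble(primaryid = demo$primaryid, pt_name = "PYREXIA")
  write_table(demo, dir, "demo.txt")
  write_table(drug, dir, "drug.txt")
  write_table(reac, dir, "reac.txt")
  write_table(tibble::tibble(primaryid = character(),
                             outcome_code = character()),
              dir, "outc.txt")
  stub_tables(dir, demo$primaryid)
  writeLines("102", file.path(dir, "deleted.txt"))
  dir
}

# direct constructor for a case set with known characteristics
make_cases <- function(cases, drugs = NULL, reactions = NULL,
                       outcomes = NULL) {
  cases <- tibble::as_tibble(cases)
  cases$caseid <- as.character(cases$caseid)
  n <- nrow(cases)
  base <- tibble::tibble(
    caseid = cases$caseid,
    primaryid = as.character(seq_len(n)),
    submission_date = as.Date("2020-06-15"),
    sex = NA_character_, age_years = NA_real_, weight_kg = NA_real_,
    reporter_type = "other", country = "US", onset_days = NA_integer_
  )
  for (nm in setdiff(names(cases), "caseid")) base[[nm]] <- cases[[nm]]
  if (is.null(drugs)) {
    drugs <- tibble::tibble(caseid = base$caseid, primaryid = base$primaryid,
                            drug_seq = "1", role_code = "PS",
                            drugname_raw = "HEMANGEOL",
                            drugname = "HEMANGEOL")
  }
  if (is.null(reactions)) {
    reactions <- tibble::tibble(caseid = base$caseid, pt_name = "EVENT A")
  }
  if (is.null(outcomes)) {
    outcomes <- tibble::tibble(caseid = character(),
                               outcome_code = character())
  }
  faersignal:::new_faers_cases(base, tibble::as_tibble(drugs),
                               tibble::as_tibble(reactions),
                               tibble::as_tibble(outcomes))
}

# nested-loop recount of the contingency cells, independent of the
# vectorised implementation
brute_force_tables <- function(cohort, background) {
  cohort_sets <- split(cohort$reactions$pt_name, cohort$reactions$caseid)
  bg_sets <- split(background$reactions$pt_name, background$reactions$caseid)
  pts <- sort(unique(unlist(cohort_sets)))
  n_cohort <- faersignal::n_cases(cohort)
  n_bg <- faersignal::n_cases(background)
  out <- lapply(pts, function(pt) {
    a <- 0L
    for (s in cohort_sets) if (pt %in% s) a <- a + 1L
    cc <- 0L
    for (s in bg_sets) if (pt %in% s) cc <- cc + 1L
    tibble::tibble(pt_name = pt, a = a, b = n_cohort - a, c = cc,
                   d = n_bg - cc)
  })
  dplyr::bind_rows(out)
}

# textbook chi-square: sum over cells of (O - E)^2 / E with E from margins
chi2_oracle <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum((o - e)^2 / e)
}

random_table <- function(max_cell = 50) {
  cells <- sample.int(max_cell, 4, replace = TRUE)
  list(a = cells[1], b = cells[2], c = cells[3], d = cells[4])
}

run_synthetic_pipeline <- function(cfg, pt_soc = NULL,
                                   policy = faersignal::pt_filter_policy(),
                                   ...) {
  g <- faersignal::generate_faers(cfg)
  cases <- suppressMessages(faersignal::deduplicate(g$quarter))
  cohort <- faersignal::select_cohort(cases)
  bg <- faersignal::cases_subset(cases, cohort$cases$caseid, negate = TRUE)
  tables <- suppressWarnings(faersignal::build_contingency(
    cohort, bg, pt_soc %||% g$pt_soc))
  filtered <- faersignal::apply_pt_filters(tables, policy)
  list(truth = g$truth, cases = cases, cohort = cohort, background = bg,
       tables = tables,
       signals = faersignal::disproportionality(filtered, ...))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
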