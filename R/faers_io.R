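## Ingestion of FAERS-style quarterly ASCII tables and case deduplication.
##
## A "quarter" is the seven dollar-delimited core tables (DEMO, DRUG, REAC,
## OUTC, RPSR, THER, INDI) plus a deleted-case list. Tables are kept as
## character tibbles exactly as read; typing (ids, dates, ages) happens in
## deduplicate(), so a write/read round trip is the identity.

faers_table_names <- c("demo", "drug", "reac", "outc", "rpsr", "ther", "indi")

faers_required_cols <- list(
  demo = c("primaryid", "caseid", "case_version", "submission_date",
           "age_value", "age_unit", "sex", "weight_kg", "reporter_type",
           "reporter_country", "event_date"),
  drug = c("primaryid", "drug_seq", "role_code", "drugname"),
  reac = c("primaryid", "pt_name"),
  outc = c("primaryid", "outcome_code"),
  rpsr = c("primaryid"),
  ther = c("primaryid", "drug_seq", "therapy_start_date"),
  indi = c("primaryid", "drug_seq", "indication_pt")
)

faers_role_codes <- c("PS", "SS", "C", "I")
faers_outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

new_faers_quarter <- function(tables, deleted, load_report) {
  structure(
    c(tables, list(deleted = deleted, load_report = load_report)),
    class = "faers_quarter"
  )
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat("<faers_quarter>\n")
  for (tb in faers_table_names) {
    cat(sprintf("  %-5s %6d rows\n", tb, nrow(x[[tb]])))
  }
  cat(sprintf("  deleted caseids: %d\n", length(x$deleted)))
  dropped <- sum(x$load_report$rows_dropped)
  if (dropped > 0) cat(sprintf("  rows dropped at load: %d\n", dropped))
  invisible(x)
}

#' Read one FAERS-style quarter
#'
#' Reads the seven core tables (dollar-delimited, one header line) and the
#' deleted-case list from a directory. Headers are matched case-insensitively
#' against the expected column names; rows whose `primaryid` is not numeric
#' are dropped and counted in the attached load report.
#'
#' @param dir directory containing the quarter files.
#' @param files named character vector of file names within `dir`; defaults
#'   to `demo.txt`, `drug.txt`, ..., `deleted.txt`.
#' @param delim field delimiter, `"$"` as in real FAERS quarters.
#' @param encoding file encoding; latin-1 (with replacement) matches the
#'   real files.
#' @return a `faers_quarter`: list of character tibbles `demo`, `drug`,
#'   `reac`, `outc`, `rpsr`, `ther`, `indi`, a character vector `deleted` of
#'   caseids, and a `load_report` tibble (`table`, `rows_read`,
#'   `rows_dropped`).
#' @seealso [deduplicate()], [write_quarter()]
#' @export
read_quarter <- function(dir,
                         files = NULL,
                         delim = "$",
                         encoding = "latin1") {
  defaults <- stats::setNames(
    paste0(c(faers_table_names, "deleted"), ".txt"),
    c(faers_table_names, "deleted")
  )
  if (!is.null(files)) defaults[names(files)] <- files
  files <- defaults

  tables <- list()
  report <- list()
  for (tb in faers_table_names) {
    path <- file.path(dir, files[[tb]])
    if (!file.exists(path)) {
      abort_format(sprintf("missing %s table file: %s", toupper(tb), path))
    }
    x <- readr::read_delim(
      path,
      delim = delim,
      col_types = readr::cols(.default = readr::col_character()),
      locale = readr::locale(encoding = encoding),
      na = character(),
      trim_ws = TRUE,
      progress = FALSE,
      show_col_types = FALSE
    )
    names(x) <- tolower(names(x))
    missing_cols <- setdiff(faers_required_cols[[tb]], names(x))
    if (length(missing_cols)) {
      abort_format(sprintf(
        "table %s is missing mandatory column(s): %s",
        toupper(tb), paste(missing_cols, collapse = ", ")
      ))
    }
    ok <- grepl("^[0-9]+$", trimws(x$primaryid %||% ""))
    report[[tb]] <- tibble(
      table = tb, rows_read = nrow(x), rows_dropped = sum(!ok)
    )
    tables[[tb]] <- x[ok, , drop = FALSE]
  }
  if (nrow(tables$demo) == 0L) {
    abort_format("DEMO table has no parseable rows; cannot build any case")
  }

  del_path <- file.path(dir, files[["deleted"]])
  deleted <- if (file.exists(del_path)) {
    d <- trimws(readLines(del_path, warn = FALSE))
    d[nzchar(d)]
  } else {
    character()
  }

  new_faers_quarter(tables, deleted, bind_rows(report))
}

#' Write a quarter to disk
#'
#' Emits the dialect [read_quarter()] reads: seven dollar-delimited tables
#' with a header line, plus `deleted.txt` with one caseid per line.
#'
#' @param quarter a `faers_quarter` (e.g. from [generate_faers()]).
#' @param dir output directory (created if needed).
#' @param delim field delimiter.
#' @return `dir`, invisibly.
#' @export
write_quarter <- function(quarter, dir, delim = "$") {
  stopifnot(inherits(quarter, "faers_quarter"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in faers_table_names) {
    readr::write_delim(quarter[[tb]], file.path(dir, paste0(tb, ".txt")),
                       delim = delim, na = "")
  }
  writeLines(as.character(quarter$deleted), file.path(dir, "deleted.txt"))
  invisible(dir)
}

#' Convert a reported age to years
#'
#' FAERS ages carry a unit code: decades (`DEC`), years (`YR`), months
#' (`MON`), weeks (`WK`), days (`DY`) or hours (`HR`). Conversion uses
#' DEC x 10, MON / 12, WK / 52, DY / 365.25, HR / 8766. Missing values,
#' unknown units and negative ages yield `NA`.
#'
#' @param age_value numeric (or character) vector of reported age values.
#' @param age_unit character vector of unit codes.
#' @return numeric vector of ages in years.
#' @examples
#' normalize_age(c(6, 2, 18), c("MON", "DEC", "YR"))
#' @export
normalize_age <- function(age_value, age_unit) {
  v <- suppressWarnings(as.numeric(age_value))
  u <- toupper(trimws(as.character(age_unit)))
  factor_by_unit <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
                      DY = 1 / 365.25, HR = 1 / 8766)
  f <- unname(factor_by_unit[u])
  out <- v * f
  n_neg <- sum(!is.na(out) & out < 0)
  if (n_neg > 0) {
    warning(sprintf("%d negative age(s) set to missing", n_neg), call. = FALSE)
    out[!is.na(out) & out < 0] <- NA_real_
  }
  out
}

map_reporter_type <- function(x) {
  x <- toupper(trimws(as.character(x)))
  dplyr::case_when(
    x %in% c("MD", "PH", "HP", "OT", "RN") ~ "health_professional",
    x %in% c("CN", "CONSUMER") ~ "consumer",
    TRUE ~ "other"
  )
}

#' Deduplicate reports into cases
#'
#' A safety case may be submitted several times; for each `caseid` only the
#' report with the latest submission date is kept (ties broken by the larger
#' `primaryid`, a proxy for later sequence). Cases on any deleted list are
#' then removed, and the child tables (drugs, reactions, outcomes, therapy
#' dates) are joined through the surviving `primaryid`.
#'
#' @param quarters a `faers_quarter` or a list of them.
#' @param counting `"case"` (default) deduplicates to one record per caseid;
#'   `"report"` keeps every report version as its own analysis unit (for
#'   sensitivity analysis) while still honouring the deleted list.
#' @return a `faers_cases` object: tibbles `cases` (caseid, primaryid,
#'   submission_date, sex, age_years, weight_kg, reporter_type, country,
#'   onset_days), `drugs` (caseid, role_code, drugname_raw, drugname),
#'   `reactions` (caseid, pt_name; one row per distinct case-PT pair) and
#'   `outcomes` (caseid, outcome_code), plus a `log` tibble of stage counts.
#'   Cases with no reaction rows are dropped (counted in the log): a safety
#'   case without an adverse event is not analysable.
#' @export
deduplicate <- function(quarters, counting = c("case", "report")) {
  counting <- match.arg(counting)
  if (inherits(quarters, "faers_quarter")) quarters <- list(quarters)
  stopifnot(length(quarters) >= 1L,
            all(vapply(quarters, inherits, logical(1), "faers_quarter")))

  demo <- bind_rows(lapply(quarters, `[[`, "demo"))
  drug <- bind_rows(lapply(quarters, `[[`, "drug"))
  reac <- bind_rows(lapply(quarters, `[[`, "reac"))
  outc <- bind_rows(lapply(quarters, `[[`, "outc"))
  ther <- bind_rows(lapply(quarters, `[[`, "ther"))
  deleted <- unique(unlist(lapply(quarters, `[[`, "deleted")))

  n_reports <- nrow(demo)
  sub <- parse_faers_date(demo$submission_date)
  demo <- demo |>
    mutate(
      .pid = as.numeric(.data$primaryid),
      .sub_date = sub$date,
      .sub_exact = sub$exact
    )

  if (counting == "case") {
    ties <- demo |>
      count(.data$caseid, .data$.sub_date) |>
      filter(.data$n > 1L)
    if (nrow(ties) > 0) {
      message(sprintf(
        "deduplicate: %d caseid(s) had tied submission dates; kept the larger primaryid",
        length(unique(ties$caseid))
      ))
    }
    o <- order(demo$caseid, demo$.sub_date, demo$.pid)
    demo <- demo[o, , drop = FALSE]
    demo <- demo[!duplicated(demo$caseid, fromLast = TRUE), , drop = FALSE]
  } else {
    # report-level units: every version stands alone, keyed by primaryid
    demo <- mutate(demo, caseid = as.character(.data$.pid))
  }

  n_after_dedup <- nrow(demo)
  demo <- filter(demo, !(.data$caseid %in% deleted))
  n_after_deleted <- nrow(demo)

  keep_pid <- demo$primaryid
  ev <- parse_faers_date(demo$event_date)

  drugs <- drug |>
    filter(.data$primaryid %in% keep_pid) |>
    left_join(select(demo, "primaryid", "caseid"), by = "primaryid") |>
    transmute(
      caseid = .data$caseid,
      primaryid = .data$primaryid,
      drug_seq = .data$drug_seq,
      role_code = toupper(trimws(.data$role_code)),
      drugname_raw = .data$drugname,
      drugname = normalize_drug_name(.data$drugname)
    )
  bad_roles <- setdiff(unique(drugs$role_code), faers_role_codes)
  if (length(bad_roles)) {
    warning(sprintf("unknown drug role code(s): %s",
                    paste(bad_roles, collapse = ", ")), call. = FALSE)
  }

  reactions <- reac |>
    filter(.data$primaryid %in% keep_pid) |>
    left_join(select(demo, "primaryid", "caseid"), by = "primaryid") |>
    transmute(caseid = .data$caseid, pt_name = normalize_pt(.data$pt_name)) |>
    filter(nzchar(.data$pt_name)) |>
    distinct()

  outcomes <- outc |>
    filter(.data$primaryid %in% keep_pid) |>
    left_join(select(demo, "primaryid", "caseid"), by = "primaryid") |>
    transmute(caseid = .data$caseid,
              outcome_code = toupper(trimws(.data$outcome_code))) |>
    filter(.data$outcome_code %in% faers_outcome_codes) |>
    distinct()

  # therapy start: PS drug's start where available, else earliest exact start
  ther_start <- ther |>
    filter(.data$primaryid %in% keep_pid) |>
    left_join(select(drugs, "primaryid", "drug_seq", "role_code"),
              by = c("primaryid", "drug_seq"))
  ts <- parse_faers_date(ther_start$therapy_start_date)
  ther_start <- ther_start |>
    mutate(start_date = ts$date, start_exact = ts$exact) |>
    filter(.data$start_exact) |>
    left_join(select(demo, "primaryid", "caseid"), by = "primaryid")
  # PS start when present, else earliest exact start: sort PS rows first,
  # then by date, and keep the first row per case
  o2 <- order(ther_start$caseid, !(ther_start$role_code %in% "PS"),
              ther_start$start_date)
  ther_start <- ther_start[o2, , drop = FALSE]
  ther_start <- ther_start[!duplicated(ther_start$caseid), , drop = FALSE] |>
    select("caseid", therapy_start = "start_date")

  cases <- demo |>
    transmute(
      caseid = .data$caseid,
      primaryid = .data$primaryid,
      submission_date = .data$.sub_date,
      sex = dplyr::if_else(toupper(trimws(.data$sex)) %in% c("F", "M"),
                           toupper(trimws(.data$sex)), NA_character_),
      age_years = suppressWarnings(
        normalize_age(.data$age_value, .data$age_unit)
      ),
      weight_kg = {
        w <- suppressWarnings(as.numeric(.data$weight_kg))
        dplyr::if_else(!is.na(w) & w >= 0, w, NA_real_)
      },
      reporter_type = map_reporter_type(.data$reporter_type),
      country = dplyr::na_if(trimws(.data$reporter_country), ""),
      event_date = ev$date,
      event_exact = ev$exact
    ) |>
    left_join(ther_start, by = "caseid") |>
    mutate(
      onset_days = {
        d <- as.integer(.data$event_date - .data$therapy_start)
        dplyr::if_else(.data$event_exact & !is.na(.data$therapy_start) &
                         !is.na(d) & d >= 0L, d, NA_integer_)
      }
    ) |>
    select(-"event_exact", -"therapy_start")

  with_reac <- cases$caseid %in% reactions$caseid
  n_no_reaction <- sum(!with_reac)
  cases <- cases[with_reac, , drop = FALSE]
  keep <- cases$caseid
  drugs <- filter(drugs, .data$caseid %in% keep)
  reactions <- filter(reactions, .data$caseid %in% keep)
  outcomes <- filter(outcomes, .data$caseid %in% keep)

  log <- tibble(
    stage = c("reports", "after_dedup", "after_deleted", "cases"),
    count = c(n_reports, n_after_dedup, n_after_deleted, nrow(cases))
  )
  if (n_no_reaction > 0) {
    message(sprintf("deduplicate: dropped %d case(s) with no reaction rows",
                    n_no_reaction))
  }

  new_faers_cases(cases, drugs, reactions, outcomes, log)
}

new_faers_cases <- function(cases, drugs, reactions, outcomes,
                            log = tibble(stage = character(),
                                         count = integer())) {
  structure(
    list(cases = as_tibble(cases), drugs = as_tibble(drugs),
         reactions = as_tibble(reactions), outcomes = as_tibble(outcomes),
         log = log),
    class = "faers_cases"
  )
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("<faers_cases> %d cases, %d drug rows, %d distinct case-PT pairs\n",
              nrow(x$cases), nrow(x$drugs), nrow(x$reactions)))
  invisible(x)
}

#' Number of cases in a `faers_cases` object
#' @param x a `faers_cases` object.
#' @return integer case count.
#' @export
n_cases <- function(x) {
  stopifnot(inherits(x, "faers_cases"))
  nrow(x$cases)
}

#' Subset cases by caseid
#'
#' @param x a `faers_cases` object.
#' @param caseids caseids to keep (or drop).
#' @param negate if `TRUE`, keep the complement (e.g. the background of a
#'   cohort).
#' @return a `faers_cases` with only the selected cases; order preserved.
#' @export
cases_subset <- function(x, caseids, negate = FALSE) {
  stopifnot(inherits(x, "faers_cases"))
  keep <- x$cases$caseid %in% caseids
  if (negate) keep <- !keep
  ids <- x$cases$caseid[keep]
  new_faers_cases(
    x$cases[keep, , drop = FALSE],
    filter(x$drugs, .data$caseid %in% ids),
    filter(x$reactions, .data$caseid %in% ids),
    filter(x$outcomes, .data$caseid %in% ids),
    x$log
  )
}
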