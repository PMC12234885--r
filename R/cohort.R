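## Primary-suspect cohort construction and Table-2-style characteristics.

#' Cohort specification
#'
#' Which cases belong to the study cohort: those reporting one of the target
#' trade names with the required drug role. The defaults target propranolol
#' oral solution via its trade names.
#'
#' @param trade_names character vector of trade names (normalized with
#'   [normalize_drug_name()] before matching).
#' @param role_required drug role code the target must carry (`"PS"` =
#'   primary suspect).
#' @param date_window optional length-2 Date vector (first, last submission
#'   date) restricting the cohort.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(trade_names = c("HEMANGEOL", "HEMANGIOL"),
                        role_required = "PS",
                        date_window = NULL) {
  stopifnot(length(trade_names) >= 1L,
            role_required %in% faers_role_codes)
  if (!is.null(date_window)) {
    stopifnot(length(date_window) == 2L)
    date_window <- as.Date(date_window)
  }
  structure(
    list(trade_names = normalize_drug_name(trade_names),
         role_required = role_required,
         date_window = date_window),
    class = "cohort_spec"
  )
}

#' Select the target-drug cohort
#'
#' Keeps cases having at least one drug with the required role and a
#' normalized name among the trade names. Input order is preserved and the
#' operation is idempotent.
#'
#' @param cases a `faers_cases` object (deduplicated).
#' @param spec a [cohort_spec()].
#' @return a `faers_cases` with only cohort cases; empty with a warning when
#'   nothing matches.
#' @export
select_cohort <- function(cases, spec = cohort_spec()) {
  stopifnot(inherits(cases, "faers_cases"), inherits(spec, "cohort_spec"))
  hit <- cases$drugs |>
    filter(.data$role_code == spec$role_required,
           .data$drugname %in% spec$trade_names) |>
    pull("caseid") |>
    unique()
  if (!is.null(spec$date_window)) {
    in_window <- cases$cases |>
      filter(!is.na(.data$submission_date),
             .data$submission_date >= spec$date_window[1],
             .data$submission_date <= spec$date_window[2]) |>
      pull("caseid")
    hit <- intersect(hit, in_window)
  }
  if (length(hit) == 0L) {
    warning(sprintf("no case matches trade names %s with role %s",
                    paste(spec$trade_names, collapse = "/"),
                    spec$role_required), call. = FALSE)
  }
  cases_subset(cases, hit)
}

#' Stratification bands for cohort characteristics
#'
#' @param age_breaks ages (years) splitting the age strata; the default
#'   single break at 1 year gives `<1` / `>=1`.
#' @param weight_breaks weights (kg) splitting the weight strata.
#' @param onset_breaks upper edges (days) of the onset bands.
#' @param year_break first calendar year of the final reporting-year band.
#' @return a `cohort_bands` list.
#' @export
cohort_bands <- function(age_breaks = 1,
                         weight_breaks = c(4.5, 8.5, 12.5),
                         onset_breaks = c(30, 60, 90, 120, 150),
                         year_break = 2024) {
  structure(list(age_breaks = age_breaks, weight_breaks = weight_breaks,
                 onset_breaks = onset_breaks, year_break = year_break),
            class = "cohort_bands")
}

band_numeric <- function(x, breaks) {
  # strata labelled "<b1", "b1-b2", ..., ">=bk"; NA -> "Missing"
  labs <- character(length(breaks) + 1L)
  labs[1] <- paste0("<", breaks[1])
  if (length(breaks) > 1L) {
    labs[2:length(breaks)] <-
      paste0(breaks[-length(breaks)], "-", breaks[-1])
  }
  labs[length(labs)] <- paste0(">=", breaks[length(breaks)])
  idx <- findInterval(x, breaks) + 1L
  out <- labs[idx]
  out[is.na(x)] <- "Missing"
  list(value = out, levels = c(labs, "Missing"))
}

band_onset <- function(x, breaks) {
  lo <- c(0, breaks[-length(breaks)] + 1)
  labs <- c(paste0(lo, "-", breaks), paste0(">", breaks[length(breaks)]))
  idx <- findInterval(x, breaks + 1L) + 1L
  out <- labs[idx]
  out[is.na(x)] <- "Missing"
  list(value = out, levels = c(labs, "Missing"))
}

# Most serious outcome per case; cases with no outcome code are non-serious.
outcome_priority <- c(DE = "death", LT = "life_threatening",
                      DS = "disability", HO = "hospitalization",
                      CA = "other_serious", RI = "other_serious",
                      OT = "other_serious")
outcome_levels <- c("death", "life_threatening", "disability",
                    "hospitalization", "other_serious", "non_serious")

classify_outcomes <- function(cases) {
  rank <- c(DE = 1, LT = 2, DS = 3, HO = 4, CA = 5, RI = 5, OT = 5)
  oc <- cases$outcomes
  o <- order(oc$caseid, rank[oc$outcome_code])
  oc <- oc[o, , drop = FALSE]
  worst <- oc[!duplicated(oc$caseid), , drop = FALSE]
  worst$code <- worst$outcome_code
  out <- rep("non_serious", nrow(cases$cases))
  m <- match(cases$cases$caseid, worst$caseid)
  hit <- !is.na(m)
  out[hit] <- unname(outcome_priority[worst$code[m[hit]]])
  out
}

#' Summarize cohort characteristics
#'
#' Stratified counts and percentages for sex, age, weight, reporter type,
#' reporting country, reporting year, most-serious outcome, and days to
#' onset. Percentages are of the cohort size, rounded half-up to one
#' decimal; within each variable the counts (including the missing-data
#' stratum) sum to the cohort size. A case with several outcome codes is
#' assigned the most serious one (death > life-threatening > disability >
#' hospitalization > other serious), and cases with no outcome code count as
#' non-serious.
#'
#' @param cohort a non-empty `faers_cases` object.
#' @param bands a [cohort_bands()] stratification spec.
#' @return a `cohort_summary` tibble with columns `variable`, `level`,
#'   `count`, `percentage`, and attributes `n_cases`.
#' @export
summarize_cohort <- function(cohort, bands = cohort_bands()) {
  stopifnot(inherits(cohort, "faers_cases"), n_cases(cohort) > 0L)
  cs <- cohort$cases
  n <- nrow(cs)

  tally <- function(variable, value, levels) {
    counts <- table(factor(value, levels = levels))
    tibble(
      variable = variable,
      level = levels,
      count = as.integer(counts[levels]),
      percentage = round_half_up(100 * as.integer(counts[levels]) / n, 1)
    )
  }

  sex <- dplyr::case_when(cs$sex == "F" ~ "Female", cs$sex == "M" ~ "Male",
                          TRUE ~ "Missing")
  age <- band_numeric(cs$age_years, bands$age_breaks)
  wt <- band_numeric(cs$weight_kg, bands$weight_breaks)

  country <- dplyr::case_when(is.na(cs$country) ~ "Missing",
                              toupper(cs$country) == "US" ~ "US",
                              TRUE ~ "non-US")

  yr <- as.integer(format(cs$submission_date, "%Y"))
  yb <- bands$year_break
  known_yr <- yr[!is.na(yr)]
  early_lab <- if (length(known_yr) && any(known_yr < yb)) {
    paste0(min(known_yr[known_yr < yb]), "-", yb - 1L)
  } else {
    paste0("<", yb)
  }
  yr_lab <- dplyr::case_when(
    is.na(yr) ~ "Missing",
    yr < yb ~ early_lab,
    TRUE ~ paste0(">=", yb)
  )
  yr_levels <- unique(c(sort(unique(yr_lab[yr_lab != "Missing"])), "Missing"))

  onset <- band_onset(cs$onset_days, bands$onset_breaks)

  out <- bind_rows(
    tally("sex", sex, c("Female", "Male", "Missing")),
    tally("age_years", age$value, age$levels),
    tally("weight_kg", wt$value, wt$levels),
    tally("reporter", cohort$cases$reporter_type,
          c("health_professional", "consumer", "other")),
    tally("country", country,
          intersect(c("US", "non-US", "Missing"), unique(country))),
    tally("reporting_year", yr_lab, yr_levels),
    tally("outcome", classify_outcomes(cohort), outcome_levels),
    tally("onset_days", onset$value, onset$levels)
  )
  structure(out, class = c("cohort_summary", class(out)), n_cases = n)
}

#' Write a cohort summary as CSV
#' @param summary a `cohort_summary` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(summary, path) {
  readr::write_csv(as_tibble(summary), path)
  invisible(path)
}
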