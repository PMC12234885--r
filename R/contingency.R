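## Per-PT 2x2 contingency tables against the full-database background.
##
## For each preferred term occurring in the cohort:
##   a = cohort cases with the PT        b = cohort cases without it
##   c = background cases with the PT    d = background cases without it
## A case contributes at most once to a (or c) per PT regardless of how many
## times the PT is mentioned on the report.

#' Read a PT-to-SOC mapping table
#'
#' The MedDRA dictionary is proprietary, so the grouping of preferred terms
#' into system organ classes is supplied by the user as a small CSV with
#' columns `pt_name`, `soc_name`, `soc_code`.
#'
#' @param path CSV file path.
#' @return tibble with normalized `pt_name`, `soc_name`, `soc_code`.
#' @export
read_pt_soc <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(x) <- tolower(names(x))
  need <- c("pt_name", "soc_name", "soc_code")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort_format(sprintf("pt_to_soc map is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  x |>
    transmute(pt_name = normalize_pt(.data$pt_name),
              soc_name = as.character(.data$soc_name),
              soc_code = as.character(.data$soc_code)) |>
    distinct(.data$pt_name, .keep_all = TRUE)
}

#' Build per-PT contingency tables
#'
#' @param cohort `faers_cases` with the target-drug cases.
#' @param background `faers_cases` with every other deduplicated case
#'   (cohort and background must be disjoint).
#' @param pt_soc tibble mapping `pt_name` to `soc_name`/`soc_code` (see
#'   [read_pt_soc()]); PTs absent from the map are kept with SOC `UNMAPPED`
#'   and a warning.
#' @return tibble with one row per distinct cohort PT: `pt_name`,
#'   `soc_name`, `soc_code`, `a`, `b`, `c`, `d`, `n_total`.
#' @export
build_contingency <- function(cohort, background, pt_soc = NULL) {
  stopifnot(inherits(cohort, "faers_cases"),
            inherits(background, "faers_cases"))
  overlap <- intersect(cohort$cases$caseid, background$cases$caseid)
  if (length(overlap)) {
    rlang::abort(sprintf(
      "cohort and background overlap on %d caseid(s); background must be the complement",
      length(overlap)))
  }
  n_cohort <- n_cases(cohort)
  n_bg <- n_cases(background)

  a_tab <- cohort$reactions |>
    distinct(.data$caseid, .data$pt_name) |>
    count(.data$pt_name, name = "a")
  c_tab <- background$reactions |>
    distinct(.data$caseid, .data$pt_name) |>
    count(.data$pt_name, name = "c")

  tables <- a_tab |>
    left_join(c_tab, by = "pt_name") |>
    mutate(
      c = dplyr::coalesce(.data$c, 0L),
      b = n_cohort - .data$a,
      d = n_bg - .data$c,
      n_total = .data$a + .data$b + .data$c + .data$d
    )

  if (!is.null(pt_soc)) {
    tables <- left_join(tables, pt_soc, by = "pt_name")
  } else {
    tables$soc_name <- NA_character_
    tables$soc_code <- NA_character_
  }
  n_unmapped <- sum(is.na(tables$soc_name))
  if (n_unmapped > 0) {
    warning(sprintf("%d PT(s) missing from the pt_to_soc map; set to UNMAPPED",
                    n_unmapped), call. = FALSE)
    tables$soc_name[is.na(tables$soc_name)] <- "UNMAPPED"
    tables$soc_code[is.na(tables$soc_code)] <- "UNMAPPED"
  }

  tables |>
    select("pt_name", "soc_name", "soc_code", "a", "b", "c", "d", "n_total") |>
    arrange(desc(.data$a), .data$pt_name)
}

#' PT filter policy
#'
#' Disproportionality on very small counts is unstable, so PTs with fewer
#' than `min_a` cohort cases are excluded, together with terms that are
#' vague, nonspecific or biologically implausible for the study drug (the
#' defaults suit an infantile-hemangioma indication), and optionally
#' everything outside a set of SOC codes.
#'
#' @param min_a minimum cohort count `a` (default 3).
#' @param exclude PT names to drop regardless of count.
#' @param soc_scope optional character vector of SOC codes to keep.
#' @return a `pt_filter_policy` list.
#' @export
pt_filter_policy <- function(min_a = 3,
                             exclude = c("ILLNESS", "CONDITION AGGRAVATED",
                                         "HAEMANGIOMA", "COVID-19"),
                             soc_scope = NULL) {
  stopifnot(min_a >= 1)
  structure(list(min_a = min_a, exclude = normalize_pt(exclude),
                 soc_scope = if (is.null(soc_scope)) NULL
                             else as.character(soc_scope)),
            class = "pt_filter_policy")
}

#' Apply the PT filter policy
#'
#' @param tables contingency tibble from [build_contingency()].
#' @param policy a [pt_filter_policy()].
#' @return the surviving tables, sorted by descending `a` (PT name breaks
#'   ties).
#' @export
apply_pt_filters <- function(tables, policy = pt_filter_policy()) {
  stopifnot(inherits(policy, "pt_filter_policy"))
  out <- tables |>
    filter(.data$a >= policy$min_a,
           !(.data$pt_name %in% policy$exclude))
  if (!is.null(policy$soc_scope)) {
    out <- filter(out, .data$soc_code %in% policy$soc_scope)
  }
  arrange(out, desc(.data$a), .data$pt_name)
}
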