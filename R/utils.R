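#' @importFrom rlang .data %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

#' Round half away from zero
#'
#' Conventional "half-up" rounding as used for display of counts and
#' percentages (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, 62.775), c(0, 0, 1))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Parse FAERS-style dates
#'
#' Dates arrive as `YYYYMMDD` strings; truncated forms (`YYYYMM`, `YYYY`) are
#' common in real submissions. Truncated forms are resolved to the first day
#' of the period so they can still order reports during deduplication, but
#' they are flagged inexact and never used for onset arithmetic, which avoids
#' fabricating day-level precision.
#'
#' @param x character (or numeric) vector of dates.
#' @return a tibble with columns `date` (Date, `NA` if unparseable) and
#'   `exact` (logical, `TRUE` only for valid 8-digit dates).
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x) | is.na(x)] <- NA_character_
  out <- rep(as.Date(NA), length(x))
  full <- !is.na(x) & grepl("^[0-9]{8}$", x)
  ym <- !is.na(x) & grepl("^[0-9]{6}$", x)
  yy <- !is.na(x) & grepl("^[0-9]{4}$", x)
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  out[ym] <- as.Date(paste0(x[ym], "01"), format = "%Y%m%d")
  out[yy] <- as.Date(paste0(x[yy], "0101"), format = "%Y%m%d")
  tibble(date = out, exact = full & !is.na(out))
}

# Dosage-form tokens stripped from the tail of verbatim drug names.
faers_dosage_tokens <- c(
  "ORAL SOLUTION", "SOLUTION", "ORAL", "TABLET", "TABLETS", "CAPSULE",
  "CAPSULES", "SYRUP", "INJECTION", "SUSPENSION", "CREAM", "GEL"
)

#' Normalize a verbatim drug name
#'
#' Uppercases, collapses whitespace, and strips trailing dosage-form tokens
#' (e.g. `"Hemangeol oral solution"` becomes `"HEMANGEOL"`). Matching against
#' a trade-name list is exact after this normalization: no fuzzy matching, so
#' cohort membership is deterministic and auditable.
#'
#' @param x character vector of drug names.
#' @param strip character vector of dosage-form tokens to strip from the end.
#' @return normalized character vector.
#' @examples
#' normalize_drug_name("  Hemangeol Oral Solution ")
#' @export
normalize_drug_name <- function(x, strip = faers_dosage_tokens) {
  x <- toupper(trimws(as.character(x)))
  x <- gsub("\\s+", " ", x)
  strip <- strip[order(-nchar(strip))]
  repeat {
    hit <- FALSE
    for (tok in strip) {
      suf <- paste0(" ", tok)
      m <- !is.na(x) & endsWith(x, suf)
      if (any(m)) {
        x[m] <- substr(x[m], 1L, nchar(x[m]) - nchar(suf))
        x[m] <- trimws(x[m])
        hit <- TRUE
      }
    }
    if (!hit) break
  }
  x
}

#' Normalize a MedDRA preferred term
#'
#' PT matching throughout the package is case-insensitive exact after
#' trimming; no dictionary hierarchy traversal is attempted.
#'
#' @param x character vector of PT names.
#' @return normalized (uppercase, squished) character vector.
#' @export
normalize_pt <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("\\s+", " ", x)
}

abort_stat <- function(msg) {
  rlang::abort(msg, class = "faersignal_undefined_statistic")
}

abort_format <- function(msg) {
  rlang::abort(msg, class = "faersignal_format_error")
}

abort_infeasible <- function(msg) {
  rlang::abort(msg, class = "faersignal_infeasible")
}
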