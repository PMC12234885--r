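## The four disproportionality statistics with interval bounds and flags.
##
## All four act on the per-PT 2x2 table (a, b, c, d), N = a+b+c+d:
##   ROR  = ad/bc,              CI = exp(ln ROR +/- 1.96*sqrt(1/a+1/b+1/c+1/d))
##   PRR  = a(c+d) / (c(a+b));  chi2 = (ad-bc)^2 N / ((a+b)(c+d)(a+c)(b+d))
##   IC   = log2(aN / ((a+b)(a+c))), CI = IC +/- 2*sqrt(V(IC))
##   EBGM = aN / ((a+c)(a+b)),  CI = exp(ln EBGM +/- 1.96*sqrt(1/a+1/b+1/c+1/d))
##
## Note that EBGM here is the unshrunk relative reporting ratio (observed
## over expected), so IC = log2(EBGM) identically; no gamma-Poisson
## shrinkage is applied. This follows the source analysis rather than
## DuMouchel's MGPS estimator, and will overstate signals at very small
## counts relative to shrunk EBGM values.

# cells enter as counts, possibly integer; products like (a+b)(c+d)(a+c)(b+d)
# overflow 32-bit integers at database scale, so everything is double
as_cells <- function(a, b, c, d) {
  list(a = as.numeric(a), b = as.numeric(b),
       c = as.numeric(c), d = as.numeric(d))
}

check_cells <- function(a, b, c, d, need_positive = c("a", "b", "c", "d")) {
  cells <- list(a = a, b = b, c = c, d = d)
  for (nm in need_positive) {
    bad <- !is.na(cells[[nm]]) & cells[[nm]] <= 0
    if (any(bad)) {
      abort_stat(sprintf(
        "statistic undefined: cell '%s' is zero in %d table(s); use the Haldane-Anscombe correction or drop the table",
        nm, sum(bad)))
    }
  }
  invisible(NULL)
}

haldane <- function(a, b, c, d) {
  zero <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  list(a = a + 0.5 * zero, b = b + 0.5 * zero,
       c = c + 0.5 * zero, d = d + 0.5 * zero, corrected = zero)
}

#' Reporting odds ratio with 95% CI
#'
#' `ROR = ad/bc` with the log-normal interval
#' `exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param a,b,c,d cells of the 2x2 table(s); vectors are accepted.
#' @param correction if `TRUE`, tables containing a zero cell get the
#'   Haldane-Anscombe 0.5 added to all four cells (flagged in the output);
#'   if `FALSE` (default) a zero cell raises a typed error naming the cell.
#' @return tibble with `ror`, `ror_low`, `ror_high` (and `corrected` when
#'   `correction = TRUE`).
#' @examples
#' compute_ror(10, 90, 100, 9900)
#' @export
compute_ror <- function(a, b, c, d, correction = FALSE) {
  cells <- as_cells(a, b, c, d)
  a <- cells$a; b <- cells$b; c <- cells$c; d <- cells$d
  if (correction) {
    h <- haldane(a, b, c, d)
    a <- h$a; b <- h$b; c <- h$c; d <- h$d
  } else {
    check_cells(a, b, c, d)
  }
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  out <- tibble(ror = ror,
                ror_low = exp(log(ror) - 1.96 * se),
                ror_high = exp(log(ror) + 1.96 * se))
  if (correction) out$corrected <- h$corrected
  out
}

#' Proportional reporting ratio and Pearson chi-square
#'
#' `PRR = a(c+d) / (c(a+b))` and the uncorrected Pearson statistic
#' `chi2 = (ad-bc)^2 (a+b+c+d) / ((a+b)(c+d)(a+c)(b+d))` (no Yates
#' continuity correction).
#'
#' @inheritParams compute_ror
#' @return tibble with `prr`, `chi2`.
#' @examples
#' compute_prr_chi2(10, 90, 100, 9900)
#' @export
compute_prr_chi2 <- function(a, b, c, d, correction = FALSE) {
  cells <- as_cells(a, b, c, d)
  a <- cells$a; b <- cells$b; c <- cells$c; d <- cells$d
  if (correction) {
    h <- haldane(a, b, c, d)
    a <- h$a; b <- h$b; c <- h$c; d <- h$d
  } else {
    check_cells(a, b, c, d, need_positive = c("a", "c"))
    bad_margin <- (a + b) <= 0 | (c + d) <= 0 | (a + c) <= 0 | (b + d) <= 0
    if (any(bad_margin)) {
      abort_stat("chi-square undefined: a zero margin in the 2x2 table")
    }
  }
  n <- a + b + c + d
  prr <- (a * (c + d)) / (c * (a + b))
  chi2 <- (a * d - b * c)^2 * n / ((a + b) * (c + d) * (a + c) * (b + d))
  tibble(prr = prr, chi2 = chi2)
}

# Closed-form moments of the information component posterior of
# Bate et al. (1998), with the customary priors alpha1 = beta1 = 1,
# alpha = beta = 2, gamma11 = 1 and gamma tuned so the prior IC is 0.
bate_ic_moments <- function(a, b, c, d) {
  n <- a + b + c + d
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  g <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  e_ic <- log((a + g11) * (n + al) * (n + be) /
                ((n + g) * (a + b + a1) * (a + c + b1))) / log(2)
  v_ic <- ((n - a + g - g11) / ((a + g11) * (1 + n + g)) +
             (n - (a + b) + al - a1) / ((a + b + a1) * (1 + n + al)) +
             (n - (a + c) + be - b1) / ((a + c + b1) * (1 + n + be))) /
    log(2)^2
  list(e = e_ic, v = v_ic)
}

#' BCPNN information component with 95% interval
#'
#' `IC = log2(aN / ((a+b)(a+c)))`, the log2 observed-over-expected
#' co-reporting ratio, with interval `E(IC) +/- 2*sqrt(V(IC))`. The variance
#' is not pinned down by the usual presentation of the method, so two
#' choices are offered: `"delta"` (default), the delta-method variance on
#' the log2 scale, `sqrt(V) = sqrt(1/a+1/b+1/c+1/d) / ln 2`, structurally
#' consistent with the EBGM interval; and `"bate"`, the closed-form Bayesian
#' posterior moments of Bate et al. (1998), in which case the interval is
#' centred on the posterior expectation rather than the raw IC.
#'
#' @inheritParams compute_ror
#' @param variance `"delta"` or `"bate"`.
#' @return tibble with `ic`, `ic025`, `ic975`.
#' @examples
#' compute_ic(10, 90, 100, 9900)
#' @export
compute_ic <- function(a, b, c, d, variance = c("delta", "bate"),
                       correction = FALSE) {
  variance <- match.arg(variance)
  cells <- as_cells(a, b, c, d)
  a <- cells$a; b <- cells$b; c <- cells$c; d <- cells$d
  if (correction) {
    h <- haldane(a, b, c, d)
    a <- h$a; b <- h$b; c <- h$c; d <- h$d
  } else if (variance == "delta") {
    check_cells(a, b, c, d)
  } else {
    check_cells(a, b, c, d, need_positive = "a")
  }
  n <- a + b + c + d
  ic <- log2(a * n / ((a + b) * (a + c)))
  if (variance == "delta") {
    sd_ic <- sqrt(1 / a + 1 / b + 1 / c + 1 / d) / log(2)
    tibble(ic = ic, ic025 = ic - 2 * sd_ic, ic975 = ic + 2 * sd_ic)
  } else {
    m <- bate_ic_moments(a, b, c, d)
    tibble(ic = ic, ic025 = m$e - 2 * sqrt(m$v), ic975 = m$e + 2 * sqrt(m$v))
  }
}

#' Empirical Bayes geometric mean (unshrunk) with 95% CI
#'
#' `EBGM = aN / ((a+c)(a+b))`, the relative reporting ratio, with the
#' log-normal interval `exp(ln EBGM +/- 1.96 * sqrt(1/a+1/b+1/c+1/d))`.
#' No gamma-Poisson shrinkage is applied (see the note at the top of the
#' statistics documentation), so `log2(ebgm)` equals the information
#' component exactly.
#'
#' @inheritParams compute_ror
#' @return tibble with `ebgm`, `ebgm05`, `ebgm95`.
#' @examples
#' compute_ebgm(10, 90, 100, 9900)
#' @export
compute_ebgm <- function(a, b, c, d, correction = FALSE) {
  cells <- as_cells(a, b, c, d)
  a <- cells$a; b <- cells$b; c <- cells$c; d <- cells$d
  if (correction) {
    h <- haldane(a, b, c, d)
    a <- h$a; b <- h$b; c <- h$c; d <- h$d
  } else {
    check_cells(a, b, c, d)
  }
  n <- a + b + c + d
  ebgm <- a * n / ((a + c) * (a + b))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble(ebgm = ebgm,
         ebgm05 = exp(log(ebgm) - 1.96 * se),
         ebgm95 = exp(log(ebgm) + 1.96 * se))
}

#' Signal thresholds
#'
#' The customary decision rules: ROR positive when the CI lower bound
#' exceeds 1 with `a >= 3`; PRR positive when `PRR >= 2`, `chi2 >= 4` and
#' `a >= 3`; BCPNN positive when `IC025 > 0`; MGPS positive when
#' `EBGM05 > 2`.
#'
#' @param ror_ci_low_gt ROR CI lower-bound cutoff (exclusive).
#' @param min_a minimum case count for the ROR and PRR rules.
#' @param prr_min PRR cutoff (inclusive).
#' @param chi2_min chi-square cutoff (inclusive).
#' @param ic025_gt IC lower-bound cutoff (exclusive).
#' @param ebgm05_gt EBGM lower-bound cutoff (exclusive).
#' @return a `signal_thresholds` list.
#' @export
signal_thresholds <- function(ror_ci_low_gt = 1, min_a = 3, prr_min = 2,
                              chi2_min = 4, ic025_gt = 0, ebgm05_gt = 2) {
  thr <- list(ror_ci_low_gt = ror_ci_low_gt, min_a = min_a,
              prr_min = prr_min, chi2_min = chi2_min, ic025_gt = ic025_gt,
              ebgm05_gt = ebgm05_gt)
  stopifnot(all(vapply(thr, is.numeric, logical(1))))
  structure(thr, class = "signal_thresholds")
}

#' Apply the per-algorithm signal flags
#'
#' Adds (or recomputes) the boolean columns `ror_pos`, `prr_pos`,
#' `bcpnn_pos`, `mgps_pos`, `any_pos`, `all_pos` from the statistic columns
#' and the raw case count `a`.
#'
#' @param stats tibble with columns `a`, `ror_low`, `prr`, `chi2`, `ic025`,
#'   `ebgm05` (as produced by [disproportionality()]).
#' @param thresholds a [signal_thresholds()].
#' @return `stats` with the flag columns set.
#' @export
flag_signals <- function(stats, thresholds = signal_thresholds()) {
  stopifnot(inherits(thresholds, "signal_thresholds"))
  stats |>
    mutate(
      ror_pos = .data$ror_low > thresholds$ror_ci_low_gt &
        .data$a >= thresholds$min_a,
      prr_pos = .data$prr >= thresholds$prr_min &
        .data$chi2 >= thresholds$chi2_min &
        .data$a >= thresholds$min_a,
      bcpnn_pos = .data$ic025 > thresholds$ic025_gt,
      mgps_pos = .data$ebgm05 > thresholds$ebgm05_gt,
      any_pos = .data$ror_pos | .data$prr_pos | .data$bcpnn_pos |
        .data$mgps_pos,
      all_pos = .data$ror_pos & .data$prr_pos & .data$bcpnn_pos &
        .data$mgps_pos
    )
}

#' Compute all four statistics and flags for a set of tables
#'
#' @param tables contingency tibble from [build_contingency()] (columns
#'   `pt_name`, `soc_name`, `soc_code`, `a`, `b`, `c`, `d`).
#' @param thresholds a [signal_thresholds()].
#' @param ic_variance `"delta"` or `"bate"` (see [compute_ic()]).
#' @param correction `"none"` (zero cells raise a typed error) or
#'   `"haldane"` (0.5 added to all cells of zero-containing tables; those
#'   rows are marked in the `corrected` column). The flag gate on `a` always
#'   uses the raw count.
#' @return a signal-statistics tibble: identifiers, raw cells, `ror`,
#'   `ror_low`, `ror_high`, `prr`, `chi2`, `ic`, `ic025`, `ic975`, `ebgm`,
#'   `ebgm05`, `ebgm95`, `corrected`, and the per-algorithm flags.
#' @export
disproportionality <- function(tables,
                               thresholds = signal_thresholds(),
                               ic_variance = c("delta", "bate"),
                               correction = c("none", "haldane")) {
  ic_variance <- match.arg(ic_variance)
  correction <- match.arg(correction)
  corr <- correction == "haldane"
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d

  out <- bind_cols(
    tables[intersect(c("pt_name", "soc_name", "soc_code",
                       "a", "b", "c", "d", "n_total"), names(tables))],
    compute_ror(a, b, c, d, correction = corr)[c("ror", "ror_low", "ror_high")],
    compute_prr_chi2(a, b, c, d, correction = corr),
    compute_ic(a, b, c, d, variance = ic_variance, correction = corr),
    compute_ebgm(a, b, c, d, correction = corr)
  )
  out$corrected <- if (corr) haldane(a, b, c, d)$corrected else FALSE
  out <- flag_signals(out, thresholds)
  attr(out, "ic_variance") <- ic_variance
  attr(out, "correction") <- correction
  out
}

#' Reconstruct a 2x2 table from published summary statistics
#'
#' Given the case count `a`, the target-drug total `a + b`, and the printed
#' PRR and (unshrunk) EBGM of one signal, the PRR and EBGM equations form a
#' linear system in the unknown background cells. The closed-form solution
#' is `c = a(EBGM - 1)/(PRR - EBGM)` and `N = EBGM (a+b)(a+c)/a`, with
#' `d = N - a - b - c`; cells are rounded to integers. This inverts a
#' published signal row back into a full table, e.g. to recompute its ROR.
#' When `PRR = EBGM = 1` (an independence row) the system is degenerate and
#' the minimal balanced table `(a, b, a, b)` is returned.
#'
#' @param a cohort cases with the event.
#' @param ab cohort size (`a + b`).
#' @param prr printed proportional reporting ratio.
#' @param ebgm printed (unshrunk) empirical Bayes geometric mean.
#' @param pt_name optional PT label for the returned row.
#' @return one-row contingency tibble (`pt_name`, `a`, `b`, `c`, `d`,
#'   `n_total`).
#' @examples
#' reconstruct_margins(a = 131, ab = 7518, prr = 84.11, ebgm = 82.85)
#' @export
reconstruct_margins <- function(a, ab, prr, ebgm, pt_name = "reconstructed") {
  stopifnot(length(a) == 1L, a >= 1, ab > a, prr > 0, ebgm > 0)
  eps <- 1e-9
  if (abs(prr - ebgm) < eps) {
    if (abs(prr - 1) < eps) {
      cc <- a
      n <- 2 * ab
    } else {
      abort_infeasible(
        "PRR and EBGM are equal but not 1: the linear system has no solution")
    }
  } else {
    cc <- a * (ebgm - 1) / (prr - ebgm)
    n <- ebgm * ab * (a + cc) / a
  }
  cc <- round(cc)
  n <- round(n)
  d <- n - ab - cc
  if (cc <= 0 || d <= 0) {
    abort_infeasible(sprintf(
      "reconstructed cells are not positive (c = %.0f, d = %.0f); inputs infeasible",
      cc, d))
  }
  tibble(pt_name = pt_name, soc_name = NA_character_,
         soc_code = NA_character_, a = a, b = ab - a, c = cc, d = d,
         n_total = n)
}
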