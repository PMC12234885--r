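## Seeded FAERS-like data generator with known ground truth.
##
## Sampling model: each case has one primary drug (the target drug for
## exactly n_target cases, otherwise uniform over the other drugs) which
## carries the PS role with probability ps_fraction (SS otherwise), plus a
## Poisson number of concomitant drugs. The case draws k ~ truncated
## Poisson(lambda), k >= 1, reaction mentions i.i.d. from the event
## distribution of its primary drug: background probabilities multiplied by
## the planted relative risks and renormalized per drug. Mentions may repeat
## a PT (as real reports do); the distinct-PT set defines the case's
## reactions. Duplicate submissions re-emit a case under a new primaryid
## with a later submission date; deleted caseids go on the deletion list.

synthetic_soc_table <- function() {
  tibble(
    soc_name = c("Vascular disorders", "Cardiac disorders",
                 "Gastrointestinal disorders", "Nervous system disorders",
                 "Respiratory disorders", "Infections and infestations",
                 "Psychiatric disorders", "Metabolism and nutrition disorders",
                 "General disorders", "Skin disorders"),
    soc_code = c("10047065", "10007541", "10017947", "10029205", "10038738",
                 "10021881", "10037175", "10027433", "10018065", "10040785")
  )
}

#' Synthetic generator configuration
#'
#' Defaults describe a mid-sized spontaneous-reporting extract whose cohort
#' resembles an infant oral-solution population: heavy age missingness
#' (83.3%), some sex (12.6%) and weight (20.0%) missingness, onset dates
#' known for only 5.7% of cases, a 20% duplicate-submission rate and a 1%
#' deletion rate. Background event frequencies follow a Zipf law.
#'
#' @param n_cases number of unique cases to generate.
#' @param n_drugs number of distinct drugs (including the target).
#' @param n_events number of distinct event PTs.
#' @param target_drug_name trade name of the study drug.
#' @param n_target exact number of cases whose primary drug is the target.
#' @param ps_fraction probability the primary drug carries the PS role.
#' @param background_event_probs event probabilities (length `n_events`,
#'   summing to 1); default Zipf (prob proportional to 1/rank).
#' @param planted_pairs tibble/data.frame with columns `drug`, `event`,
#'   `rr`: relative reporting-rate multipliers applied before per-drug
#'   renormalization.
#' @param events_per_case_lambda mean of the truncated (>= 1) Poisson count
#'   of reaction mentions per case.
#' @param duplication_rate probability a case is re-submitted once.
#' @param deletion_rate probability a case lands on the deleted list.
#' @param missingness list with elements `age`, `sex`, `weight` giving the
#'   per-field missing-data rates.
#' @param onset_known_rate probability the event date (hence onset) is
#'   recorded.
#' @param seed integer RNG seed; everything derives from it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_cases = 20000,
                             n_drugs = 50,
                             n_events = 200,
                             target_drug_name = "HEMANGEOL",
                             n_target = round(0.05 * n_cases),
                             ps_fraction = 0.9,
                             background_event_probs = NULL,
                             planted_pairs = NULL,
                             events_per_case_lambda = 3,
                             duplication_rate = 0.2,
                             deletion_rate = 0.01,
                             missingness = list(age = 0.833, sex = 0.126,
                                                weight = 0.200),
                             onset_known_rate = 0.057,
                             seed = 1L) {
  if (is.null(background_event_probs)) {
    w <- 1 / seq_len(n_events)
    background_event_probs <- w / sum(w)
  }
  if (length(background_event_probs) != n_events ||
      any(background_event_probs < 0) ||
      abs(sum(background_event_probs) - 1) > 1e-8) {
    rlang::abort("background_event_probs must be length n_events, nonnegative, and sum to 1",
                 class = "faersignal_config_error")
  }
  if (!is.null(planted_pairs)) {
    planted_pairs <- as_tibble(planted_pairs)
    stopifnot(all(c("drug", "event", "rr") %in% names(planted_pairs)),
              all(planted_pairs$rr > 0))
  } else {
    planted_pairs <- tibble(drug = character(), event = character(),
                            rr = numeric())
  }
  stopifnot(
    n_cases >= 1, n_drugs >= 2, n_events >= 2,
    n_target >= 0, n_target <= n_cases,
    ps_fraction >= 0, ps_fraction <= 1,
    events_per_case_lambda > 0,
    duplication_rate >= 0, duplication_rate < 1,
    deletion_rate >= 0, deletion_rate < 1,
    all(unlist(missingness) >= 0), all(unlist(missingness) <= 1),
    onset_known_rate >= 0, onset_known_rate <= 1
  )
  structure(
    list(n_cases = as.integer(n_cases), n_drugs = as.integer(n_drugs),
         n_events = as.integer(n_events),
         target_drug_name = normalize_drug_name(target_drug_name),
         n_target = as.integer(n_target), ps_fraction = ps_fraction,
         background_event_probs = background_event_probs,
         planted_pairs = planted_pairs,
         events_per_case_lambda = events_per_case_lambda,
         duplication_rate = duplication_rate, deletion_rate = deletion_rate,
         missingness = missingness, onset_known_rate = onset_known_rate,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

synthetic_drug_names <- function(cfg) {
  c(cfg$target_drug_name, sprintf("DRUG%03d", seq_len(cfg$n_drugs - 1L)))
}

synthetic_event_names <- function(cfg) {
  sprintf("EVT%03d", seq_len(cfg$n_events))
}

#' Deterministic PT-to-SOC map for synthetic events
#'
#' Events are assigned round-robin to ten SOCs (the first being Vascular
#' disorders, code 10047065, the second Cardiac disorders, 10007541), so
#' every tenth event starting at EVT001 is "vascular" and so on.
#'
#' @param cfg a [synthetic_config()].
#' @return tibble `pt_name`, `soc_name`, `soc_code`.
#' @export
synthetic_pt_soc <- function(cfg) {
  socs <- synthetic_soc_table()
  idx <- ((seq_len(cfg$n_events) - 1L) %% nrow(socs)) + 1L
  tibble(pt_name = synthetic_event_names(cfg),
         soc_name = socs$soc_name[idx],
         soc_code = socs$soc_code[idx])
}

# per-drug event distribution after planting and renormalization
drug_event_probs <- function(cfg, drug) {
  events <- synthetic_event_names(cfg)
  w <- cfg$background_event_probs
  pp <- cfg$planted_pairs[cfg$planted_pairs$drug == drug, , drop = FALSE]
  if (nrow(pp)) {
    j <- match(pp$event, events)
    if (anyNA(j)) {
      rlang::abort("planted event not among synthetic events",
                   class = "faersignal_config_error")
    }
    w[j] <- w[j] * pp$rr
  }
  w / sum(w)
}

rtpois <- function(n, lambda) {
  # truncated Poisson, k >= 1, via inverse-cdf on the conditional tail
  stats::qpois(stats::runif(n, stats::ppois(0, lambda), 1), lambda)
}

#' Generate a synthetic FAERS-style quarter
#'
#' Fully reproducible from `cfg$seed`; the same configuration yields
#' byte-identical files. Ground truth (unique-case counts, the per-PT cohort
#' and background case counts, cohort size, planted pairs) is computed on
#' the surviving cases (after deletion), so it is directly comparable with
#' the output of the deduplication pipeline.
#'
#' @param cfg a [synthetic_config()].
#' @param dir optional output directory; when given, the seven tables,
#'   `deleted.txt`, `pt_soc.csv`, ground-truth CSVs and a YAML echo of the
#'   configuration are written there.
#' @return list with `quarter` (a `faers_quarter`), `truth` (list:
#'   `n_unique`, `n_reports`, `n_cohort`, `event_counts` tibble with
#'   `pt_name`, `a_true`, `c_true`, `planted`), `pt_soc`, and `config`.
#' @export
generate_faers <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, generate_faers_impl(cfg, dir))
}

generate_faers_impl <- function(cfg, dir) {
  n <- cfg$n_cases
  drugs <- synthetic_drug_names(cfg)
  events <- synthetic_event_names(cfg)

  caseid <- 100000L + seq_len(n)
  primaryid <- caseid * 10 + 1

  is_target <- rep(FALSE, n)
  if (cfg$n_target > 0) is_target[sample.int(n, cfg$n_target)] <- TRUE
  primary_drug <- ifelse(
    is_target, cfg$target_drug_name,
    sample(drugs[-1], n, replace = TRUE)
  )
  primary_role <- ifelse(stats::runif(n) < cfg$ps_fraction, "PS", "SS")

  # reaction mentions, i.i.d. within case given the primary drug
  k <- rtpois(n, cfg$events_per_case_lambda)
  case_of_mention <- rep.int(seq_len(n), k)
  mention_event <- character(length(case_of_mention))
  planted_drugs <- unique(cfg$planted_pairs$drug)
  drug_class <- ifelse(primary_drug %in% planted_drugs, primary_drug, ".bg")
  for (cl in unique(drug_class)) {
    p <- if (cl == ".bg") cfg$background_event_probs
         else drug_event_probs(cfg, cl)
    sel <- drug_class[case_of_mention] == cl
    mention_event[sel] <- sample(events, sum(sel), replace = TRUE, prob = p)
  }

  # demographics
  miss <- cfg$missingness
  sex <- ifelse(stats::runif(n) < miss$sex, "",
                ifelse(stats::runif(n) < 0.718, "F", "M"))
  age_known <- stats::runif(n) >= miss$age
  infant <- stats::runif(n) < 0.815
  age_value <- ifelse(age_known,
                      ifelse(infant, sample(1:11, n, replace = TRUE),
                             sample(1:10, n, replace = TRUE)),
                      NA)
  age_unit <- ifelse(age_known, ifelse(infant, "MON", "YR"), "")
  wt_known <- stats::runif(n) >= miss$weight
  wt_band <- sample.int(4, n, replace = TRUE,
                        prob = c(0.077, 0.565, 0.286, 0.072))
  wt_lo <- c(2.5, 4.5, 8.5, 12.5)[wt_band]
  wt_hi <- c(4.5, 8.5, 12.5, 18)[wt_band]
  weight_kg <- ifelse(wt_known,
                      sprintf("%.1f", wt_lo + stats::runif(n) * (wt_hi - wt_lo)),
                      "")
  reporter_draw <- stats::runif(n)
  reporter <- ifelse(reporter_draw < 0.666,
                     sample(c("MD", "PH"), n, replace = TRUE),
                     ifelse(reporter_draw < 0.921, "CN", "LW"))
  country <- ifelse(stats::runif(n) < 0.966, "US",
                    sample(c("FR", "GB", "DE", "CN", "JP"), n, replace = TRUE))

  days <- seq(as.Date("2014-01-01"), as.Date("2024-09-30"), by = "day")
  submission <- sample(days, n, replace = TRUE)
  therapy_start <- submission - sample(30:400, n, replace = TRUE)
  onset_known <- stats::runif(n) < cfg$onset_known_rate
  onset_band <- sample.int(6, n, replace = TRUE,
                           prob = c(102, 21, 20, 14, 19, 45) / 221)
  band_lo <- c(0, 31, 61, 91, 121, 151)[onset_band]
  band_hi <- c(30, 60, 90, 120, 150, 330)[onset_band]
  onset_days <- band_lo +
    floor(stats::runif(n) * (band_hi - band_lo + 1))
  event_date <- ifelse(onset_known,
                       format(therapy_start + onset_days, "%Y%m%d"), "")

  # outcomes: at most one serious code per case; none -> non-serious
  oc_draw <- stats::runif(n)
  outcome <- dplyr::case_when(
    oc_draw < 0.002 ~ "DE",
    oc_draw < 0.005 ~ "LT",
    oc_draw < 0.0055 ~ "DS",
    oc_draw < 0.042 ~ "HO",
    oc_draw < 0.080 ~ sample(c("CA", "RI", "OT"), n, replace = TRUE),
    TRUE ~ ""
  )

  # concomitant drugs (never the target, so cohort ground truth stays exact)
  n_con <- stats::rpois(n, 0.7)
  con_case <- rep.int(seq_len(n), n_con)
  con_drug <- sample(drugs[-1], length(con_case), replace = TRUE)
  con_role <- sample(c("SS", "C", "I"), length(con_case), replace = TRUE,
                     prob = c(0.3, 0.6, 0.1))
  con_seq <- unlist(lapply(n_con[n_con > 0], function(m) seq_len(m) + 1L),
                    use.names = FALSE)

  # duplicate submissions and deletions
  dup <- stats::runif(n) < cfg$duplication_rate
  deleted_flag <- stats::runif(n) < cfg$deletion_rate
  dup_idx <- which(dup)
  dup_primaryid <- caseid[dup_idx] * 10 + 2
  dup_submission <- submission[dup_idx] + sample(1:180, length(dup_idx),
                                                 replace = TRUE)

  age_value_chr <- ifelse(is.na(age_value), "", as.character(age_value))
  demo_one <- function(idx, pid, ver, sub) {
    tibble(
      primaryid = as.character(pid),
      caseid = as.character(caseid[idx]),
      case_version = as.character(ver),
      submission_date = format(sub, "%Y%m%d"),
      age_value = age_value_chr[idx],
      age_unit = age_unit[idx],
      sex = sex[idx],
      weight_kg = weight_kg[idx],
      reporter_type = reporter[idx],
      reporter_country = country[idx],
      event_date = event_date[idx]
    )
  }
  demo <- bind_rows(
    demo_one(seq_len(n), primaryid, 1L, submission),
    demo_one(dup_idx, dup_primaryid, 2L, dup_submission)
  ) |> arrange(as.numeric(.data$primaryid))

  pid_of <- function(idx) as.character(primaryid[idx])
  drug_rows <- function(idx_map, pid) {
    bind_rows(
      tibble(primaryid = pid[idx_map(seq_len(n))],
             drug_seq = "1", role_code = primary_role,
             drugname = primary_drug,
             prod_ai = ifelse(is_target, "PROPRANOLOL HYDROCHLORIDE",
                              primary_drug)),
      tibble(primaryid = pid[idx_map(con_case)],
             drug_seq = as.character(con_seq), role_code = con_role,
             drugname = con_drug, prod_ai = con_drug)
    )
  }
  pid_all <- stats::setNames(as.character(primaryid), seq_len(n))
  drug_v1 <- drug_rows(function(i) i, pid_all)
  dup_of <- function(tb) {
    keep <- tb$primaryid %in% as.character(primaryid[dup_idx])
    out <- tb[keep, , drop = FALSE]
    out$primaryid <- as.character(
      dup_primaryid[match(out$primaryid, as.character(primaryid[dup_idx]))])
    out
  }

  drug_tab <- bind_rows(drug_v1, dup_of(drug_v1)) |>
    arrange(as.numeric(.data$primaryid), as.numeric(.data$drug_seq))

  reac_v1 <- tibble(primaryid = pid_of(case_of_mention),
                    pt_name = mention_event)
  reac_tab <- bind_rows(reac_v1, dup_of(reac_v1)) |>
    arrange(as.numeric(.data$primaryid), .data$pt_name)

  outc_v1 <- tibble(primaryid = pid_of(which(outcome != "")),
                    outcome_code = outcome[outcome != ""])
  outc_tab <- bind_rows(outc_v1, dup_of(outc_v1)) |>
    arrange(as.numeric(.data$primaryid))

  rpsr_v1 <- tibble(primaryid = pid_of(seq_len(n)),
                    rpsr_code = ifelse(country == "US", "HP", "FGN"))
  rpsr_tab <- bind_rows(rpsr_v1, dup_of(rpsr_v1)) |>
    arrange(as.numeric(.data$primaryid))

  ther_v1 <- tibble(primaryid = pid_of(seq_len(n)), drug_seq = "1",
                    therapy_start_date = format(therapy_start, "%Y%m%d"))
  ther_tab <- bind_rows(ther_v1, dup_of(ther_v1)) |>
    arrange(as.numeric(.data$primaryid))

  indi_v1 <- tibble(primaryid = pid_of(seq_len(n)), drug_seq = "1",
                    indication_pt = ifelse(is_target,
                                           "INFANTILE HAEMANGIOMA",
                                           "HYPERTENSION"))
  indi_tab <- bind_rows(indi_v1, dup_of(indi_v1)) |>
    arrange(as.numeric(.data$primaryid))

  deleted <- as.character(caseid[deleted_flag])

  load_report <- tibble(
    table = faers_table_names,
    rows_read = c(nrow(demo), nrow(drug_tab), nrow(reac_tab),
                  nrow(outc_tab), nrow(rpsr_tab), nrow(ther_tab),
                  nrow(indi_tab)),
    rows_dropped = 0L
  )
  quarter <- new_faers_quarter(
    list(demo = demo, drug = drug_tab, reac = reac_tab, outc = outc_tab,
         rpsr = rpsr_tab, ther = ther_tab, indi = indi_tab),
    deleted, load_report
  )

  # ground truth on surviving (non-deleted) unique cases
  surviving <- !deleted_flag
  in_cohort <- surviving & is_target & primary_role == "PS"
  case_event <- tibble(case = case_of_mention, pt_name = mention_event) |>
    distinct()
  case_event$cohort <- in_cohort[case_event$case]
  case_event$surv <- surviving[case_event$case]
  event_counts <- case_event |>
    filter(.data$surv) |>
    group_by(.data$pt_name) |>
    summarise(a_true = sum(.data$cohort), c_true = sum(!.data$cohort),
              .groups = "drop")

  truth <- list(
    n_unique = sum(surviving),
    n_reports = nrow(demo),
    n_cohort = sum(in_cohort),
    event_counts = event_counts,
    planted = cfg$planted_pairs
  )
  pt_soc <- synthetic_pt_soc(cfg)

  if (!is.null(dir)) {
    write_quarter(quarter, dir)
    readr::write_csv(pt_soc, file.path(dir, "pt_soc.csv"))
    readr::write_csv(event_counts, file.path(dir, "ground_truth_counts.csv"))
    readr::write_csv(
      tibble(quantity = c("n_unique", "n_reports", "n_cohort"),
             value = c(truth$n_unique, truth$n_reports, truth$n_cohort)),
      file.path(dir, "ground_truth_summary.csv")
    )
    cfg_echo <- cfg
    cfg_echo$planted_pairs <- as.data.frame(cfg$planted_pairs)
    yaml::write_yaml(unclass(cfg_echo), file.path(dir, "config.yml"))
  }

  list(quarter = quarter, truth = truth, pt_soc = pt_soc, config = cfg)
}

#' Expected contingency cells under the sampling model
#'
#' Closed-form expectations for the 2x2 cells of one drug-event pair, for
#' power analysis and test tolerances. A case with primary drug g and k
#' reaction mentions includes event e with probability
#' `1 - E[(1 - p_ge)^k]` where `p_ge` is the per-mention probability after
#' planting and renormalization and k is truncated Poisson; the per-drug
#' renormalization slightly deflates the realized relative risk, and these
#' expectations account for that. Cells refer to the deduplicated,
#' post-deletion case universe with the cohort defined as target-drug PS
#' cases.
#'
#' @param cfg a [synthetic_config()].
#' @param drug drug name (the cohort is always the target drug's PS cases;
#'   `drug` must currently be the target drug).
#' @param event event PT name.
#' @return tibble with expected `a`, `b`, `c`, `d`.
#' @export
expected_contingency <- function(cfg, drug = cfg$target_drug_name, event) {
  stopifnot(inherits(cfg, "synthetic_config"))
  events <- synthetic_event_names(cfg)
  if (!(event %in% events)) {
    rlang::abort(sprintf("unknown event '%s'", event),
                 class = "faersignal_lookup_error")
  }
  if (!identical(drug, cfg$target_drug_name)) {
    rlang::abort("expected cells are defined for the target-drug cohort",
                 class = "faersignal_lookup_error")
  }
  lam <- cfg$events_per_case_lambda
  p_hit <- function(p) {
    # P(event in case) for mention prob p, k ~ Poisson(lam) | k >= 1
    1 - (exp(-lam * p) - exp(-lam)) / (1 - exp(-lam))
  }
  j <- match(event, events)
  p_target <- drug_event_probs(cfg, cfg$target_drug_name)[j]

  other_drugs <- synthetic_drug_names(cfg)[-1]
  p_other <- vapply(other_drugs, function(g) drug_event_probs(cfg, g)[j],
                    numeric(1))

  keep <- 1 - cfg$deletion_rate
  n_t <- cfg$n_target * keep
  n_o <- (cfg$n_cases - cfg$n_target) * keep
  ps <- cfg$ps_fraction

  e_a <- n_t * ps * p_hit(p_target)
  e_b <- n_t * ps - e_a
  # background: non-target-primary cases plus target cases not in PS role
  e_c <- n_o * mean(p_hit(p_other)) + n_t * (1 - ps) * p_hit(p_target)
  e_d <- (n_o + n_t * (1 - ps)) - e_c
  tibble(a = e_a, b = e_b, c = e_c, d = e_d)
}
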