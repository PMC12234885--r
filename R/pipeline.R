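## End-to-end orchestration: read -> dedup -> cohort -> tables -> stats ->
## flags, with the run artifacts written as CSV and aligned text.

#' Pipeline run configuration
#'
#' @param input directory holding one quarter (the seven files) or several
#'   quarter subdirectories (detected by the presence of `demo.txt`).
#' @param output directory for the run artifacts (created if needed).
#' @param cohort a [cohort_spec()].
#' @param policy a [pt_filter_policy()] (applied without SOC scope to the
#'   full signal table; the cardiovascular table additionally restricts to
#'   SOC codes 10047065 and 10007541).
#' @param thresholds a [signal_thresholds()].
#' @param counting `"case"` (deduplicated cases, default) or `"report"`
#'   (every report version as its own unit, for sensitivity analysis).
#' @param ic_variance `"delta"` or `"bate"` (see [compute_ic()]).
#' @param correction `"none"` or `"haldane"` (see [disproportionality()]).
#' @param pt_soc path to a PT-to-SOC CSV, or a tibble as returned by
#'   [read_pt_soc()]; `NULL` leaves all PTs unmapped.
#' @return a `run_config` list.
#' @export
run_config <- function(input, output,
                       cohort = cohort_spec(),
                       policy = pt_filter_policy(),
                       thresholds = signal_thresholds(),
                       counting = c("case", "report"),
                       ic_variance = c("delta", "bate"),
                       correction = c("none", "haldane"),
                       pt_soc = NULL) {
  structure(
    list(input = input, output = output, cohort = cohort, policy = policy,
         thresholds = thresholds, counting = match.arg(counting),
         ic_variance = match.arg(ic_variance),
         correction = match.arg(correction), pt_soc = pt_soc),
    class = "run_config"
  )
}

cardiovascular_soc_codes <- c("10047065", "10007541")

discover_quarters <- function(input) {
  if (file.exists(file.path(input, "demo.txt"))) return(input)
  subs <- list.dirs(input, recursive = FALSE)
  subs <- subs[file.exists(file.path(subs, "demo.txt"))]
  if (!length(subs)) {
    abort_format(sprintf("no quarter (demo.txt) found under %s", input))
  }
  sort(subs)
}

log_line <- function(con, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full signal-detection pipeline
#'
#' Reads the quarter(s), deduplicates, selects the cohort, builds and
#' filters the per-PT contingency tables, computes the four statistics with
#' flags, and writes `cohort_summary.csv`, `signals_all.csv`,
#' `signals_cardiovascular.csv`, `signals_positive.csv`, a rendered
#' `signal_table.txt`, the load report, and `run_log.csv` with the stage
#' counts. An empty cohort aborts with the nearest drug-name matches as a
#' diagnostic.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a list with `cases`, `cohort`, `summary`, `tables`,
#'   `signals`, `signals_cardiovascular`, `signals_positive`, `stages`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output, "run_log.txt")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)

  qdirs <- discover_quarters(cfg$input)
  log_line(con, sprintf("reading %d quarter(s) from %s",
                        length(qdirs), cfg$input))
  quarters <- lapply(qdirs, read_quarter)
  n_reports <- sum(vapply(quarters,
                          function(q) nrow(q$demo), integer(1)))
  readr::write_csv(bind_rows(lapply(quarters, `[[`, "load_report")),
                   file.path(cfg$output, "load_report.csv"))

  cases <- deduplicate(quarters, counting = cfg$counting)
  log_line(con, sprintf("%d reports -> %d analysis units (%s counting)",
                        n_reports, n_cases(cases), cfg$counting))

  cohort <- suppressWarnings(select_cohort(cases, cfg$cohort))
  if (n_cases(cohort) == 0L) {
    all_names <- unique(cases$drugs$drugname)
    near <- unique(unlist(lapply(
      cfg$cohort$trade_names,
      function(nm) all_names[agrepl(nm, all_names, max.distance = 0.3)]
    )))
    rlang::abort(
      sprintf("empty cohort for trade names %s; nearest drug names in data: %s",
              paste(cfg$cohort$trade_names, collapse = "/"),
              paste(utils::head(near, 10), collapse = ", ")),
      class = "faersignal_empty_cohort"
    )
  }
  background <- cases_subset(cases, cohort$cases$caseid, negate = TRUE)
  log_line(con, sprintf("cohort %d, background %d",
                        n_cases(cohort), n_cases(background)))

  summary <- summarize_cohort(cohort)
  write_cohort_summary(summary, file.path(cfg$output, "cohort_summary.csv"))

  pt_soc <- cfg$pt_soc
  if (is.character(pt_soc)) pt_soc <- read_pt_soc(pt_soc)
  tables <- suppressWarnings(build_contingency(cohort, background, pt_soc))
  filtered <- apply_pt_filters(tables, cfg$policy)
  log_line(con, sprintf("%d PTs in cohort, %d after filters",
                        nrow(tables), nrow(filtered)))

  signals <- disproportionality(filtered, thresholds = cfg$thresholds,
                                ic_variance = cfg$ic_variance,
                                correction = cfg$correction)
  cardio <- filter(signals, .data$soc_code %in% cardiovascular_soc_codes)
  positive <- filter(signals, .data$any_pos)
  log_line(con, sprintf("%d positive PTs (any algorithm), %d cardiovascular PTs",
                        nrow(positive), nrow(cardio)))

  readr::write_csv(signals, file.path(cfg$output, "signals_all.csv"))
  readr::write_csv(cardio, file.path(cfg$output, "signals_cardiovascular.csv"))
  readr::write_csv(positive, file.path(cfg$output, "signals_positive.csv"))
  writeLines(render_signal_table(signals),
             file.path(cfg$output, "signal_table.txt"))

  stages <- tibble(
    stage = c("reports", "analysis_units", "cohort", "background",
              "pts_total", "pts_after_filter", "pts_positive"),
    count = c(n_reports, n_cases(cases), n_cases(cohort),
              n_cases(background), nrow(tables), nrow(filtered),
              nrow(positive))
  )
  readr::write_csv(stages, file.path(cfg$output, "run_log.csv"))

  invisible(list(cases = cases, cohort = cohort, summary = summary,
                 tables = tables, signals = signals,
                 signals_cardiovascular = cardio,
                 signals_positive = positive, stages = stages))
}
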