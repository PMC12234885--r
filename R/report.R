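## Aligned text rendering of a signal table, grouped by SOC.

fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))

#' Render a signal table as aligned text
#'
#' One block per system organ class (ordered by total case count), PTs
#' sorted by descending case count within the block, point estimates and
#' interval bounds at two decimals (half-up). An empty input renders the
#' header only.
#'
#' @param stats signal-statistics tibble from [disproportionality()].
#' @return character vector of lines.
#' @export
render_signal_table <- function(stats) {
  header <- sprintf(
    "%-28s %5s %9s %19s %9s %9s %9s %9s %9s %6s",
    "PT", "a", "ROR", "ROR 95% CI", "PRR", "chi2", "IC", "IC025",
    "EBGM", "flags"
  )
  rule <- strrep("-", nchar(header))
  lines <- c(header, rule)
  if (nrow(stats) == 0L) return(lines)

  socs <- stats |>
    group_by(.data$soc_name, .data$soc_code) |>
    summarise(total_a = sum(.data$a), .groups = "drop") |>
    arrange(desc(.data$total_a), .data$soc_name)

  for (i in seq_len(nrow(socs))) {
    block <- stats |>
      filter(.data$soc_name == socs$soc_name[i]) |>
      arrange(desc(.data$a), .data$pt_name)
    soc_lab <- if (is.na(socs$soc_code[i]) ||
                   socs$soc_code[i] == "UNMAPPED") {
      socs$soc_name[i]
    } else {
      sprintf("%s (SOC code: %s)", socs$soc_name[i], socs$soc_code[i])
    }
    lines <- c(lines, sprintf("## %s", soc_lab))
    for (j in seq_len(nrow(block))) {
      r <- block[j, ]
      flags <- paste0(
        if (r$ror_pos) "R" else ".", if (r$prr_pos) "P" else ".",
        if (r$bcpnn_pos) "B" else ".", if (r$mgps_pos) "M" else "."
      )
      lines <- c(lines, sprintf(
        "%-28s %5d %9s %9s-%9s %9s %9s %9s %9s %9s %6s",
        substr(r$pt_name, 1, 28), r$a, fmt2(r$ror), fmt2(r$ror_low),
        fmt2(r$ror_high), fmt2(r$prr), fmt2(r$chi2), fmt2(r$ic),
        fmt2(r$ic025), fmt2(r$ebgm), flags
      ))
    }
  }
  lines
}
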