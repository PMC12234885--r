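# faersignal

Disproportionality signal detection for FAERS-style spontaneous adverse
event reports.

Spontaneous-reporting databases (the FDA Adverse Event Reporting System and
its kin) have no exposure denominator, so drug-safety questions are asked by
disproportionality: for each adverse event preferred term (PT), is the pair
(drug, event) reported more often than the rest of the database predicts
under independence? `faersignal` is for pharmacovigilance analysts who work
with the quarterly ASCII extracts: it ingests the dollar-delimited
DEMO/DRUG/REAC/OUTC/RPSR/THER/INDI tables, deduplicates reports into cases
(latest submission date per caseid, deleted cases removed), selects a
primary-suspect cohort by trade name (defaults: HEMANGEOL / HEMANGIOL,
i.e. propranolol oral solution), summarises cohort characteristics, and
screens every cohort PT with the four standard statistics on the 2×2 table
(a, b, c, d; N = a+b+c+d):

| statistic | formula | positive signal |
|---|---|---|
| ROR  | ad / bc, CI = exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)) | CI lower limit > 1, a ≥ 3 |
| PRR  | a(c+d) / (c(a+b)); χ² = (ad−bc)²N / ((a+b)(c+d)(a+c)(b+d)) | PRR ≥ 2, χ² ≥ 4, a ≥ 3 |
| BCPNN IC | log₂(aN / ((a+b)(a+c))), interval IC ± 2·√V(IC) | IC025 > 0 |
| EBGM | aN / ((a+c)(a+b)), CI = exp(ln EBGM ± 1.96·√(1/a+1/b+1/c+1/d)) | EBGM05 > 2 |

Note: EBGM here is the unshrunk relative reporting ratio (so
IC = log₂(EBGM) identically), not DuMouchel's gamma-Poisson shrinkage
estimator; see the methods vignette
(`vignettes/disproportionality-methods.Rmd`) for this and the other
documented choices (V(IC), zero-cell handling, dedup tie-breaks, outcome
priority).

A seeded synthetic generator (`generate_faers()`) emits the same multi-table
dialect with known ground truth — planted drug–event relative risks,
duplicate and deleted cases, realistic missingness — so the whole pipeline
is testable without a database download.

## Worked example

Simulate a quarter with a planted tenfold association between the target
drug and a vascular-SOC event, then run the pipeline:

```r
library(faersignal)

cfg <- synthetic_config(
  n_cases = 4000, n_drugs = 10, n_events = 40, n_target = 600, seed = 57,
  planted_pairs = data.frame(drug = "HEMANGEOL", event = "EVT011", rr = 10)
)
generate_faers(cfg, dir = "demo_quarter")

res <- run_pipeline(run_config(
  input = "demo_quarter", output = "demo_out",
  pt_soc = "demo_quarter/pt_soc.csv"
))
res$stages
#> # A tibble: 7 × 2
#>   stage            count
#>   <chr>            <int>
#> 1 reports           4824
#> 2 analysis_units    3966
#> 3 cohort             532
#> 4 background        3434
#> 5 pts_total           40
#> 6 pts_after_filter    40
#> 7 pts_positive         1
```

4,824 reports collapse to 3,966 deduplicated cases (the generator's 20%
duplication rate plus deletions), 532 of which carry the target drug as
primary suspect. Of 40 candidate PTs, exactly one is flagged — the planted
pair:

```r
head(res$signals[order(-res$signals$ror), ], 3)
#>   pt_name soc_code     a   ror ror_low   prr   chi2    ic  ebgm all_pos
#> 1 EVT011  10047065   238 11.9    9.59   7.05 667.   1.96   3.89 TRUE
#> 2 EVT023  10017947    23  1.48   0.930  1.46   2.76 0.456  1.37 FALSE
#> 3 EVT019  10018065    22  1.32   0.824  1.30   1.33 0.324  1.25 FALSE
```

EVT011 is reported in 238 of the 532 cohort cases; its ROR of 11.9 (95% CI
9.59–14.87) and the other three statistics all clear their thresholds
(`all_pos`), while every unplanted PT stays quiet. `demo_out/` contains
`cohort_summary.csv`, `signals_all.csv`, `signals_cardiovascular.csv`
(vascular + cardiac SOCs), `signals_positive.csv`, the stage counts, and an
aligned text table:

```
PT                               a       ROR          ROR 95% CI       PRR      chi2        IC     IC025      EBGM  flags
-------------------------------------------------------------------------------------------------------------------------
## Vascular disorders (SOC code: 10047065)
EVT001                         250      0.78      0.65-     0.94      0.89      6.79     -0.15     -0.42      0.90   ....
EVT011                         238     11.94      9.59-    14.87      7.05    667.11      1.96      1.64      3.89   RPBM
```

`reconstruct_margins()` inverts a published signal row (case count, cohort
size, PRR, EBGM) back into a full 2×2 table, e.g. to recompute its ROR:

```r
t <- reconstruct_margins(a = 131, ab = 7518, prr = 84.11, ebgm = 82.85)
compute_ror(t$a, t$b, t$c, t$d)$ror
#> [1] 85.58187
```

A thin command-line front end with `simulate` and `analyze` subcommands is
in `inst/scripts/faersignal.R`.

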