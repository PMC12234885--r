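---
title: "Disproportionality signal detection on FAERS-style spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on FAERS-style spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-reporting databases such as the FDA Adverse Event Reporting
System collect safety reports on suspected drug adverse events, each
carrying demographics, one or more drugs with role codes (primary suspect,
secondary suspect, concomitant, interacting), one or more MedDRA preferred
terms (PTs) for the reactions, and outcome codes. Because there is no
denominator of exposed patients, safety questions are asked by
*disproportionality*: is a given drug–event pair reported more often than
the rest of the database would predict under independence? `faersignal`
implements that analysis end to end for a primary-suspect drug cohort —
here, by default, propranolol oral solution identified through its trade
names HEMANGEOL and HEMANGIOL — against the full-database background.

The pipeline is: read the quarterly tables, deduplicate reports into cases,
select the cohort, form one 2×2 table per PT, compute four
disproportionality statistics with interval bounds, and flag signals by the
customary thresholds.

## Case deduplication

A safety case can be submitted repeatedly (follow-ups, corrections), so
counts at the report level overstate evidence. For each `caseid` only the
report with the latest submission date is kept. Two choices here were
genuinely open and are resolved as follows:

* **Ties on submission date** are broken by the larger `primaryid`, a proxy
  for later sequence within a day; the tie is logged.
* **Truncated dates** (`YYYYMM`, `YYYY`) are resolved to the first day of
  their period for *ordering only*; they are flagged inexact and never used
  for onset arithmetic, which avoids fabricating day-level precision.
* Deduplication runs globally, before cohort restriction, matching the
  usual order of operations (deduplicate, then merge and search).

Caseids on the deleted list are removed after version selection. Cases with
no reaction rows are dropped (a safety case without an adverse event is not
analysable); the stage counts appear in the object's log and in the
pipeline's `run_log.csv`, and are monotone non-increasing from raw reports
to cohort.

Onset (days from therapy start to event) uses the primary-suspect drug's
therapy start when one is recorded, otherwise the earliest exact start;
negative differences are treated as missing data rather than evidence.

## Cohort characteristics

`summarize_cohort()` stratifies the cohort by sex, age (< 1 / ≥ 1 years by
default), weight (4.5 / 8.5 / 12.5 kg breaks), reporter type, country,
reporting year, outcome, and onset bands, each with an explicit
missing-data stratum so counts always sum to the cohort size. Percentages
are of the cohort size, rounded half-up to one decimal.

A case may carry several outcome codes; published characteristics tables
typically show outcome rows that sum to roughly the cohort size, which
requires a single outcome per case. The package assigns the most serious
code by the priority death > life-threatening > disability >
hospitalization > other serious, with code-free cases counted as
non-serious. This is a documented convention, not an inference about any
particular source's rule.

## The 2×2 tables

For each PT occurring in the cohort:

|              | target event | other events |
|--------------|--------------|--------------|
| cohort       | a            | b            |
| background   | c            | d            |

The counting unit is the deduplicated **case** (a case contributes at most
once per PT, however often the report mentions it). Report-level counting
is available as `counting = "report"` for sensitivity analysis, since
spontaneous-reporting publications sometimes mix the two units. The
background is every deduplicated case outside the cohort, regardless of
role codes — the standard full-database comparator.

PT matching is case-insensitive exact after whitespace normalization; no
MedDRA hierarchy traversal is attempted (the dictionary is proprietary), so
the PT→SOC grouping is a small user-supplied CSV. Filtering drops PTs with
`a < 3` (disproportionality is unstable at very small counts), a
configurable list of vague or implausible terms (defaults: ILLNESS,
CONDITION AGGRAVATED, HAEMANGIOMA, COVID-19), and optionally everything
outside a set of SOC codes (e.g. `c("10047065", "10007541")` for the
vascular and cardiac SOCs).

## The four statistics

With `N = a + b + c + d`:

* **ROR** `= ad/bc`, CI `exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`;
  positive when the lower bound exceeds 1 and `a ≥ 3`.
* **PRR** `= a(c+d) / (c(a+b))` with the uncorrected Pearson chi-square
  `(ad−bc)²N / ((a+b)(c+d)(a+c)(b+d))`; positive when `PRR ≥ 2`,
  `χ² ≥ 4` and `a ≥ 3`. No Yates correction is applied, matching the
  plain Pearson form.
* **IC** `= log2(aN / ((a+b)(a+c)))`, the information component, with
  interval `IC ± 2·√V(IC)`; positive when `IC025 > 0`.
* **EBGM** `= aN / ((a+c)(a+b))` with CI
  `exp(ln EBGM ± 1.96·√(1/a + 1/b + 1/c + 1/d))`; positive when
  `EBGM05 > 2`.

Two deliberate documentation-level warnings:

1. **EBGM is unshrunk.** The formula above is the raw relative reporting
   ratio (observed over expected), not DuMouchel's gamma-Poisson shrinkage
   estimator usually meant by "MGPS EBGM". It is implemented exactly as
   written, so `IC = log2(EBGM)` holds as an identity (the tests assert it
   to 1e-12), and small-count signals are *not* shrunk toward 1 the way
   MGPS practitioners may expect.
2. **V(IC) is a choice.** The IC interval's variance is not pinned down by
   the formula set above. The default is the delta-method variance on the
   log2 scale, `√V(IC) = √(1/a+1/b+1/c+1/d)/ln 2`, structurally consistent
   with the EBGM interval; `ic_variance = "bate"` switches to the
   closed-form Bayesian posterior moments of Bate et al. (1998) (priors
   α₁ = β₁ = 1, α = β = 2, γ₁₁ = 1, γ tuned to prior IC 0), in which case
   the interval is centred on the posterior mean rather than the raw IC.
   Results record which method produced them. The interval multiplier is
   ±2 standard deviations, as conventionally written for the IC, not
   ±1.96.

```{r stats-example}
disproportionality(tibble::tibble(
  pt_name = "EXAMPLE", soc_name = NA, soc_code = NA,
  a = 10L, b = 90L, c = 100L, d = 9900L
))[, c("ror", "ror_low", "prr", "chi2", "ic", "ebgm", "all_pos")]
```

### Zero cells

By default a zero cell raises a typed error naming the cell: silently
producing infinite odds ratios is worse than stopping. The
Haldane–Anscombe correction (0.5 added to all four cells of
zero-containing tables) is opt-in via `correction = "haldane"` and flags
corrected rows in the output. The `a ≥ 3` gates always use the raw count.
Cells are coerced to double before arithmetic because margin products
overflow 32-bit integers at database scale.

### Inverting published rows

`reconstruct_margins()` solves the PRR and EBGM equations for the
background cells given a published signal row (`a`, the cohort size, PRR,
EBGM): `c = a(EBGM−1)/(PRR−EBGM)` and `N = EBGM(a+b)(a+c)/a`. This lets a
published row be expanded back into a full table — for instance to
recompute its ROR as a consistency check:

```{r reconstruct}
t <- reconstruct_margins(a = 131, ab = 7518, prr = 84.11, ebgm = 82.85)
t
compute_ror(t$a, t$b, t$c, t$d)$ror
```

When PRR and EBGM are equal the system is degenerate: at 1 it returns the
balanced independence table; away from 1 it raises an infeasibility error.
Published pairs that are equal only because of two-decimal rounding (a
genuinely occurring corner) therefore cannot be inverted and the error says
so rather than guessing.

## The synthetic generator

`generate_faers()` emits the exact multi-table dialect the reader consumes,
with known ground truth, so every stage — parsing, deduplication, cohort
recovery, cell counts, signal recovery — is testable without a download.
Each case draws one primary drug (the target for exactly `n_target` cases),
which carries the PS role with probability `ps_fraction`; reaction mentions
are i.i.d. draws (truncated-Poisson many, so a PT can repeat within a
report, as in real data) from the drug's event distribution: background
probabilities times the planted relative risks, renormalized per drug.
Duplicates re-emit a case under a new `primaryid` with a later submission
date; deleted caseids go on the deletion list. Identical configuration and
seed give byte-identical files.

Default condition choices, made once:

* 20,000 cases, 50 drugs, 200 events, 5% target cases, `ps_fraction` 0.9,
  mean 3 reaction mentions per case, Zipf background event frequencies — a
  mid-sized extract with a realistically skewed event spectrum.
* Missingness: age 83.3%, sex 12.6%, weight 20.0%; onset dates known for
  5.7% of cases; reporters 66.6/25.5/7.9% health-professional, consumer,
  other; 96.6% US; 71.8% of known-sex cases female — the shape of an
  infant oral-solution cohort.
* `duplication_rate` 0.2, `deletion_rate` 0.01.

Because relative risks multiply probabilities *before* per-drug
renormalization, and because a case makes several mentions, the realized
case-level rate ratio sits somewhat below the planted `rr` for frequent
events (for a mid-rank Zipf event at rr = 10 the deflation is roughly
15–25%). `expected_contingency()` gives the exact closed-form expected
cells under the sampling model — `P(PT in case) = 1 − E[(1−p)^k]` with k
truncated Poisson — and the Monte-Carlo tests check the generator against
it to 3 standard errors. Power-style claims in the tests are therefore
stated against the model's own expectations, with planted-recovery checks
run on rarer PTs where the deflation is small.

What the generator does **not** emulate: drug co-prescription structure,
confounding between demographics and events, masking/competition bias, and
duplicate reports that differ in content. Passing tests on synthetic data
show the machinery is correct under the stated sampling model, not that
real-database signals are unbiased.

## Validation problem sizes

The shipped test-suite uses: worked-example identities on published-scale
tables (seconds); null calibration on one 30,000-case database with 600
uniformly-frequent PTs, asserting the jointly-positive fraction stays at or
below 1%; planted-signal recovery (rr = 10, expected `a ≥ 30`) across 100
seeded replicates of 20,000 cases, requiring all four algorithms in at
least 95; dedup ground-truth equality over 20 seeds; and oracle equivalence
of the chi-square (1,000 random tables vs the textbook Σ(O−E)²/E form,
1e-9) and of the contingency cells (nested-loop recount on 3,000 generated
cases). These sizes were chosen to make the statistical assertions sharp at
desk scale.

## Known limitations

* No multiple-testing adjustment across PTs is applied; none is
  conventional for threshold-based signal screening, but the family-wise
  error over hundreds of PTs is real.
* The unshrunk EBGM (see above) will overstate small-count signals
  relative to MGPS.
* Exact-match drug-name normalization (uppercase, trimmed, dosage-form
  tokens stripped) is deterministic and auditable but will miss misspelled
  trade names; the empty-cohort diagnostic lists near matches to help.
* Disproportionality measures reporting associations, not causation, and
  inherits every reporting bias of the source database.
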