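---
title: "Estimating GA-window reachability from sparse ANC registers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating GA-window reachability from sparse ANC registers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancreach)
```

## The problem

Maternal immunization programs need to know what fraction of pregnant women
can be reached by an ANC clinic inside a vaccine's gestational-age window.
Routine registers in many settings record, per pregnancy, only the total
number of ANC contacts $k$, the GA in completed weeks at the first contact
$f$, and at the last contact $l$. The timing of the $k-2$ intermediate
contacts is unobserved, so reachability in any window that excludes $f$ and
$l$ must be estimated under an assumption about where those contacts fell.

`ancreach` implements that estimation: exclusion filtering with full data
accounting, three interpolation strategies, stratified and multi-country
combined estimates, and a synthetic cohort generator used to validate the
estimator against ground truth.

## Data model and filtering

A register extract is one row per pregnancy: country, clinic, calendar
year, $k$, $f$, $l$. GA is treated as completed integer weeks; fractional
values are floored on input and flagged, never excluded. Two filter stages
are applied, each attributing every excluded record to exactly one reason:

* **Descriptive stage** (contact-count analyses): drop records with no
  recorded contact count, more than 16 contacts (outlier health-seeking
  behaviour), no recorded clinic, or a single recorded contact whose first
  and last GAs differ (an internal contradiction). Precedence is fixed —
  missing count, then $>16$, then missing clinic, then the single-contact
  mismatch — which affects only the tally, never the retained set.
* **Window stage** (GA analyses): additionally drop records missing either
  GA or with $l < f$ (an extraction error). $l = f$ is valid: all contacts
  may fall in one week.

Both filters are idempotent, conserve counts (retained plus exclusions
equal input, per stratum), and their retained set is independent of row
order. No GA plausibility-range filter is applied by default because the
analysis the package implements defines none; degenerate values survive to
the estimator, whose closed support handles them.

## Interpolation strategies

All strategies keep the observed endpoints and operate on the closed
integer support $\{f, \dots, l\}$ ($m = l - f + 1$ weeks):

* **none** — the schedule is $\{f, l\}$ (or $\{f\}$ when $k = 1$): a
  conservative bound using only observed contacts.
* **even** — $k$ contacts at $f + (l-f)\,i/(k-1)$, $i = 0, \dots, k-1$,
  interior positions rounded half-up to whole weeks (deterministic and
  locale-free); endpoints never rounded.
* **random** (main) — the $k-2$ unobserved contacts i.i.d. uniform on
  $\{f,\dots,l\}$ *with replacement*, since several contacts can occur in
  the same week. With $w$ support weeks inside the window $[lo, hi]$, the
  per-record reach probability is exact:
  $$P = 1 - \left(\frac{m-w}{m}\right)^{k-2},$$
  with $P = 1$ when an endpoint lies in the window and $P = 0$ when
  $k \le 2$ and both endpoints are outside.

Two choices here were genuinely open. First, the support is *closed*
(endpoint weeks are allowed for interior contacts): an open-interval
support degenerates whenever $l - f \le 1$, while the closed form handles
every record uniformly; the effect on estimates is negligible except at
tiny spans. Second, the default estimation mode is the exact probability
rather than averaging random draws: the exact form is the infinite-draw
limit, is variance-free, and makes results reproducible without draw-count
decisions. `mc_reach_random()` retains the draw-based mode; the test suite
checks it converges to the closed form, and the closed form itself is
checked against exhaustive enumeration of all $m^{k-2}$ placements over
every short span ($l - f \le 8$, $k \le 6$) in exact arithmetic.

Randomness, where used, flows from a single cohort seed; per-record
substreams are derived from the record's row index so results do not
depend on processing order.

## Aggregation and weighting

Per-record reach values (probabilities under `random`, 0/1 indicators under
`none`/`even`) are averaged within strata: overall, country, clinic, year,
and contact-count groups ($\{1\}, \{2\text{–}3\}, \{\ge 4\}$ three-way;
$\{1\text{–}3\}, \{\ge 4\}$ two-way). Countries are combined two ways:

* **pooled** — $\sum_i p_i n_i / \sum_i n_i$: every individual equal.
* **normalized** — $\frac{1}{C}\sum_i p_i$: every country equal. For
  proportions this is *identical* to an inverse-probability-weighted
  individual mean with weights $\propto 1/n_{country}$; the suite asserts
  that identity to $10^{-12}$. The same per-individual weights extend the
  normalization to distribution summaries, where the mean-of-countries
  shortcut has no analogue for quantiles.

Medians and IQRs (contact counts, GA at first/last contact) use a weighted
quantile defined by cumulative-weight inversion: sorted values sit at
midpoint positions $(c_i - w_i/2)/W$ of the cumulative weight and quantiles
are linearly interpolated between adjacent order statistics. With equal
weights this is the familiar interpolated sample quantile (the median of
12, 14, 20, 24 is 17). Group gains are reported as absolute
percentage-point differences, $(p_{\ge4} - p_{1\text{–}3}) \times 100$,
matching how such comparisons are conventionally printed; reports round
half-up to one decimal, while all stored values keep full precision.
Strata with zero records are omitted rather than shown as zero, keeping
"no data" distinct from "no reach".

## The synthetic cohort generator

`simulate_cohort()` draws, per country: $k$ from a configurable pmf on
1–16; $f$ from a discretized normal truncated to weeks 4–40 whose mean
depends on the contact-count group (more contacts, earlier booking — means
default to 24/20/16 weeks for groups 1/2–3/$\ge4$); the span $l - f$ from a
Poisson with mean $2 + 3.2\,(\min(k,10)-1)$ truncated so $l \le 42$ (more
contacts, later last contact); and the $k-2$ interior *true* contacts from
a placement law — uniform (default), early-clustered, or late-clustered
(geometric weights with ratio 0.65 across the span). The generator emits
both the observed register row and the full true schedule, so estimator
error is measurable.

Two biasing mechanisms found in real registers are emulated. *Register
truncation*: each record with $k < 4$ is dropped with a configurable
probability (clinics that only document from the fourth contact onward);
enabling it demonstrably inflates apparent reachability. *Data errors*:
with small per-record probabilities a row loses its contact count, loses a
GA, gets its GAs swapped (forced to $l < f$ so it always surfaces in the
window filter), becomes a contradictory single-contact record, or gets an
outlier count $> 16$. Errors are injected after truncation and mutually
exclusively, so every expected exclusion tally is a closed-form binomial
mean — which the tests check to within three binomial standard deviations.

The shipped six-country presets (about 2,500 records, or 600 in the small
preset) span the heterogeneity the estimator must tolerate: a
single-contact-dominant country (share 0.52 at one contact, later
booking), a $\ge4$-dominant country with 50% sub-4 truncation, an
early-booking country, and intermediate patterns. They are illustrative
fixtures chosen once for realism, not reconstructions of any real
population, and the generator makes no attempt to reproduce seasonality,
within-month sampling designs, or pandemic-period effects beyond year
labels.

What passing tests show, and what they do not: on generator data with
uniform interior placement the random-interpolation estimate matches true
reachability to within 1.5 percentage points at $n = 20{,}000$ (it is the
correctly specified model); with early-clustered placement the estimator
*overstates* late-window (32–36 weeks) reachability — the suite asserts the
sign of that bias. Real registers may cluster contacts in unknown ways, so
the uniform-placement estimate should be read alongside the `none` lower
bound, which needs no placement assumption at all.

## Numerical and interface choices

* Problem sizes in the validation suite — enumeration over all spans with
  $l - f \le 8$ and $k \le 6$, a 20-record Monte-Carlo probe at 10,000
  draws, 1,000-case property sweeps, and 20,000-record calibration
  cohorts — were chosen to make binomial noise small relative to the
  tolerances being asserted.
* Windows parse from `"lo-hi"` strings; membership is closed on both ends.
  The four standard windows (0–23, 24–36, 28–36, 32–36 weeks) ship as
  presets.
* Degenerate inputs: empty cohorts return empty bundles with a warning;
  empty strata are omitted; $k=1$ records have $f = l$ after filtering and
  a single-week schedule under every strategy.
* The file pipeline (`run_simulate()`, `run_analyze()`, `run_report()`, and
  the thin CLI script) is byte-deterministic given config and seed; the CLI
  exits 0 on success, 2 on config errors, 3 on input-schema errors, 4 on
  internal errors.

## Known limitations

No contacts are imputed outside $[f, l]$, so reachability before the first
or after the last contact is by construction zero under every strategy.
GA dating error (fundal height vs LMP vs ultrasound) is not modelled; GA is
taken as recorded. The estimator ignores any within-woman correlation in
contact spacing beyond the endpoints. Confidence intervals are not
produced — estimates are descriptive proportions, and their dominant
uncertainty in practice is the placement assumption, which the three
strategies bracket.
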