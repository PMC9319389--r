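---
title: "Relative-weight scoring: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative-weight scoring: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relw)
```

## The model and its assumptions

`relw` scores binary diagnostic profiles with an additive, counting-based
model. The input is a *counting dataset*: for each of $k$ variables (a
symptom, or a chest-CT finding), the number $c_v$ of cohort patients
exhibiting it. Each variable's *relative weight* is

$$ w_v = \frac{c_v}{\sum_u c_u}, $$

so computed weights sum to exactly 1, are invariant to rescaling all counts,
and order variables by how often they co-occur with the diagnosed condition
in the cohort. A patient profile — a present/absent assignment over all $k$
variables — is scored

$$ +LR = \sum_{v\,\mathrm{present}} w_v, \qquad -LR = 1 - (+LR). $$

The assumptions are strong and worth stating plainly: variables contribute
independently and additively; a variable's importance is its cohort
frequency, with no adjustment for co-occurrence, severity, or a control
population; and the score is *not* a calibrated probability or a
sensitivity/specificity-based likelihood ratio, despite the field-standard
"+LR/−LR" labels, which the package keeps with this documented caveat. The
model's value is transparency: every score decomposes exactly into named
per-variable contributions, and the complete prediction surface over all
$2^k$ profiles can be enumerated and inspected.

Two variable families are supported — patient symptoms and medical-image
findings — selected by `source_kind`. The computation is identical; the
field distinguishes them only because they feed different upstream
predictive models (rules-based vs convolutional).

## Two scoring modes

Weight tables arrive two ways. `relative_weights()` computes them from
counts and guarantees $\sum w_v = 1$ (tolerance $10^{-12}$).
`load_supplied_weights()` takes pre-tabulated percents verbatim: published
tables are not always internally consistent, and the bundled 19-variable CT
table sums to 103.2%. The sum is recorded and a `normalized` flag marks
whether it lies in $[0.995, 1.005]$; nothing is rescaled, because silently
repairing a published table would misreport what the table says.

The normalization defect is why two scoring modes exist:

* `sum_present` (default): $+LR = \sum_{present} w_v$ — matches the
  published worked examples and single-present table rows;
* `complement`: $+LR = 1 - \sum_{absent} w_v$ — matches the published
  near-all-present rows of the non-normalized CT table, which were evidently
  computed as "100% minus the absent weights".

The modes coincide exactly when the table sums to 1 (property-tested), and
differ by the constant $\sum w_v - 1$ otherwise. With a non-normalized
table, `sum_present` can exceed 100%; the score is *not* clamped — a classed
warning (`relw_score_out_of_range`) is attached instead, keeping the defect
visible to the caller.

## Display rounding

All arithmetic is done at full double precision; rounding is display-only.
Percents render at 1 decimal place by default using **round-half-up**
(`render_percent()` / `percent_value()`), which reproduces every cell of the
published 15-variable symptom weight table from raw counts — base R's
`round()` is round-half-even and does not. A `truncate` mode and a `compact`
flag (printing `100` rather than `100.0`) cover the other conventions seen
in published tables. A $10^{-9}$ absolute guard absorbs binary
representation error (e.g. `164.99999999999997` for 16.5) before the floor.

The cohort's own printed count table carries a third, *prevalence-weight*
convention — count over cohort size (`prevalence_weight()`, e.g.
$14/112 = 12.5\%$). Its printed column is internally inconsistent in
places, so only exact cells are treated as reference values.

## Enumeration conventions

`enumerate_profiles()` streams all $2^k$ rows in fixed-size chunks (65,536
by default): the 19-variable table's 524,288 rows pass through in a few
seconds without ever being materialized. Row order is *binary*: counting
with the last listed variable as the least-significant bit, all-present
first (explanation 1) to all-absent (explanation $2^k$). Published tables of
this kind pin down only their first and last rows — the middle ordering is
not inferable — so this order is the package's own convention, and
`lookup_profile()` (exact random access in $O(k)$) is the supported way to
find a published row by its ± pattern. A guard refuses $k > 24$ without
`force = TRUE`; `by_lr_desc` ordering needs a full score index
($O(2^k)$ memory, a few MB at $k = 19$) and is capped at $k \le 20$.

`top_profiles()` answers "which profiles score highest" without
enumeration: for an additive score this is a $k$-best subset problem, solved
by best-first search over *dropped-variable* subsets with weights sorted
ascending. Ties (zero-weight variables create whole plateaus) are drained a
level at a time and broken by binary order, so the output is exact, not
heuristic.

Groups (fever grades; lesion distribution) are metadata by default: the
exhaustive table deliberately includes clinically contradictory rows such as
"no lesion" and "peripheral" both present, because that is what a complete
$2^k$ enumeration means. `strict_groups = TRUE` opts into at-most-one
present variable per group when scoring real patients.

## Worked-example conventions adopted

Two upstream ambiguities required a decision:

* The published formula block swaps the two labels (writing the present-sum
  as $-LR$); both worked examples use the present-sum as $+LR$, and the
  package follows the worked examples.
* The published symptom worked example lists five percent addends for four
  stated symptoms (the 17.2% term appears twice), totalling 60.3%.
  `sum_weights()` exists to audit such printed arithmetic verbatim — it sums
  a multiset of table entries, repeats allowed — while `score_profile()`
  counts each variable at most once and gives the natural four-symptom score
  of 43.1% (or 43.0% from full-precision count-derived weights; the 0.1
  difference is rounding of the published cells).

## The synthetic generator

`generate_dataset()` emulates the *structure* of a real counting cohort so
every module is property-testable on data it has never seen: $k$ variables,
optional exclusive groups, counts drawn either as a multinomial split of a
fixed count total over Dirichlet proportions (`concentration` < 1 gives the
few-dominant-symptoms shape of real tables) or as independent uniform
integers. Defaults mirror the bundled cohort: 15 variables, 112 patients, a
count total of 279, concentration 1. `sample_profiles()` draws patient
profiles with independent per-variable Bernoulli presence.

What the generator does *not* emulate: correlation between variables
(real symptoms co-occur), group exclusivity in the sampled profiles, cohort
heterogeneity, or any disease-status label. Passing property tests on
synthetic data therefore demonstrates the arithmetic and its invariants —
normalization, complementarity, monotonicity, mode equivalence, oracle
agreement — not clinical validity on real patients.

A single integer seed governs each generation call, scoped with
`withr::with_seed()` so results are reproducible and the caller's RNG state
is untouched; generator state is never shared between operations.

## Numerical choices and degenerate inputs

* Weight arithmetic: plain double summation ($k \le 24$; error far below
  display precision). Complementarity $+LR + (-LR) = 1$ holds exactly by
  construction ($-LR$ is defined as $1 - (+LR)$, never computed separately).
* Zero-weight variables are retained, not dropped; they contribute 0 to any
  score and create the tie plateaus `top_profiles()` handles explicitly.
* All-zero count vectors are a degenerate-dataset error for
  `relative_weights()` (the normalization is undefined). The synthetic
  generator nudges an all-zero draw to a single count of 1 so downstream
  properties stay testable.
* Mode-equivalence and normalization tolerances are $10^{-12}$; tie
  comparison in the top-$k$ search uses $10^{-12}$ on sums of weights.
* Variable names match exactly, case-sensitively: clinical labels embed
  parenthesized ranges that must not be normalized. Unknown names in a
  profile fail with near-match suggestions (edit distance via
  `utils::adist`).

## Problem sizes in the test suite

The suite exercises full enumerations at $k \le 10$ against a brute-force
re-summation oracle, the complete $2^{19}$ stream for row counting and
content lookups, 10,000-profile prevalence checks against a binomial
$3\sigma$ band, and a few hundred randomized scoring cases per property —
sizes chosen to pin each invariant while keeping the default run fast.

## Known limitations

* The min/max weight-bounds dialect is I/O only: no transformation from
  bounds to a single weight table is provided, because the published
  derivation is unstated and could not be reconstructed; the bundled CT
  weight table is therefore treated as supplied, not computed.
* Scores are unadjusted cohort frequencies: no smoothing or priors on
  counts, no confidence intervals, no post-test probability calculus.
* Enumeration offers no pruning or approximation; beyond $k \approx 24$ the
  table is simply not the right tool.
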