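# relw — relative-weight diagnostic scoring

`relw` implements an interpretable, counting-based scoring model for binary
diagnostic variables — patient symptoms or medical-image findings — aimed at
clinicians and modellers who need predictions they can trace back to the
features that produced them, rather than a black-box classifier output.

## The model

Given a cohort table that counts, for each of `k` variables, the number of
patients exhibiting it, each variable gets a **relative weight**

```
w_v = c_v / Σ_u c_u
```

(its count normalized by the sum of all counts, so Σ w_v = 1). A patient's
presence/absence profile is scored additively:

```
+LR = Σ_{v present} w_v        −LR = 1 − (+LR)
```

`+LR`/`−LR` follow the field's "likelihood ratio" labels, but they are
additive scores in [0, 1], not sensitivity/specificity-based likelihood
ratios. Because the score is a plain sum, the complete prediction table over
all `2^k` profiles can be enumerated and every row explained variable by
variable. Weight tables may also be supplied pre-tabulated; such tables need
not sum to 100% (one bundled table sums to 103.2%), which the package
surfaces rather than hides — a `complement` scoring mode
(`+LR = 1 − Σ_{absent} w_v`) is provided because near-all-present rows of a
non-normalized table are only reproducible that way.

The package ships the reference tables of a 112-patient COVID-19 cohort
(15 symptom variables; 19 chest-CT variables such as ground-glass opacity
and crazy-paving pattern) as plain-text fixtures; see `relw_example()`.

## Worked example

```r
library(relw)

ct  <- read_counting_dataset(relw_example("covid_ct_weights.csv"))
wt  <- load_supplied_weights(ct)       # published weights, sum 103.2%
prof <- presence_profile(ct, present = c(
  "GGO", "Bronchiectasis", "Pericardial effusion",
  "Consolidation", "Bilateral multilobe", "Peripheral"
))
res <- score_profile(prof, wt)
res
#> <score_result> +LR 59.2% / -LR 40.8% (sum_present mode)
explain(res)
#> Explanation (sum_present mode): +LR 59.2%, -LR 40.8%
#>    1. GGO                                        18.5%  (cumulative 18.5%)
#>    2. Bilateral multilobe                        13.5%  (cumulative 32.0%)
#>    3. Peripheral                                 13.1%  (cumulative 45.1%)
#>    4. Consolidation                               9.4%  (cumulative 54.5%)
#>    5. Bronchiectasis                              4.4%  (cumulative 58.9%)
#>    6. Pericardial effusion                        0.3%  (cumulative 59.2%)
#>  absent: Crazy-paving pattern, Linear opacities, Air bronchogram, ...
```

The six observed CT findings sum to a positive score of 59.2%, with GGO the
strongest contributor; the cumulative column shows how each finding moves
the score. Computing weights from counts instead:

```r
sym <- read_counting_dataset(relw_example("covid_symptom_counts.csv"))
render_percent(relative_weights(sym)$weights[["Dry Cough"]])
#> [1] "17.2%"    # 48 of 279 symptom observations
```

Enumeration, random access, and top-scoring profiles:

```r
et <- enumerate_profiles(wt)           # 2^19 = 524,288 rows, streamed
lookup_profile(presence_profile(ct, "Peripheral"), wt)$positive_lr_pct
#> [1] 13.1
top_profiles(wt, k_rows = 2)$positive_lr_pct
#> [1] 103.2 103.2   # dropping a zero-weight variable changes nothing
```

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/relw.R score inst/extdata/covid_ct_weights.csv \
  --weights supplied --present GGO --present Peripheral
```

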