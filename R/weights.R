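#' Compute relative weights from patient counts
#'
#' The model's importance measure: each variable's relative weight is its
#' patient count divided by the sum of counts over all variables,
#'
#' \deqn{w_v = \frac{c_v}{\sum_{u} c_u},}
#'
#' so computed weights always sum to exactly 1 and multiplying every count by
#' a positive constant leaves them unchanged. Full precision is kept
#' internally; rounding happens only at display time via [render_percent()].
#'
#' @param dataset A [counting_dataset()] in which every variable carries a
#'   count.
#' @return A `weight_table` with `provenance = "computed_from_counts"`.
#' @examples
#' ds <- read_counting_dataset(relw_example("covid_symptom_counts.csv"))
#' wt <- relative_weights(ds)
#' render_percent(wt$weights[["Dry Cough"]])  # 48/279 -> "17.2%"
#' @export
relative_weights <- function(dataset) {
  stopifnot(inherits(dataset, "counting_dataset"))
  counts <- dataset$variables$count
  missing <- is.na(counts)
  if (any(missing)) {
    abort_validation(sprintf(
      "Cannot compute relative weights: no count for %s.",
      comma(dataset$variables$variable[missing])
    ))
  }
  total <- sum(counts)
  if (total <= 0) {
    abort_validation(
      "Degenerate dataset: all counts are zero, relative weights are undefined."
    )
  }
  new_weight_table(
    dataset,
    weights = counts / total,
    provenance = "computed_from_counts"
  )
}

#' Prevalence weight of a single variable
#'
#' The fraction of the cohort exhibiting the variable: `count /
#' total_patients`. This is the convention of the cohort's published
#' min/max-bounds table, distinct from [relative_weights()] (which normalizes
#' by the sum of counts, not the cohort size).
#'
#' @param count Non-negative integer patient count, or a one-row slice of a
#'   dataset's `variables` table.
#' @param total_patients Positive integer cohort size.
#' @return A fraction in `[0, 1]`.
#' @examples
#' prevalence_weight(14, 112)  # 0.125 -> "12.5%"
#' @export
prevalence_weight <- function(count, total_patients) {
  if (is.data.frame(count)) count <- count$count
  if (length(count) != 1 || is.na(count) || count < 0) {
    abort_validation("`count` must be a single non-negative number.")
  }
  total_patients <- assert_count_scalar(total_patients, "total_patients")
  if (total_patients < 1L) {
    abort_validation("`total_patients` must be positive.")
  }
  if (count > total_patients) {
    abort_validation(sprintf(
      "Count (%s) exceeds the cohort size (%d).", format(count), total_patients
    ))
  }
  count / total_patients
}

#' Load a pre-tabulated (supplied) weight table
#'
#' Takes each variable's `weight_pct` verbatim as `weight_pct / 100`, without
#' renormalizing. The sum is recorded and a `normalized` flag marks whether
#' it falls in `[0.995, 1.005]`: published tables are not always consistent —
#' the bundled CT weight table sums to 103.2% — and surfacing that defect is
#' more useful than hiding it. Scoring such a table can push the positive
#' score outside `[0, 1]`, which [score_profile()] flags with a warning.
#'
#' @param dataset A [counting_dataset()] in which every variable carries
#'   `weight_pct`.
#' @return A `weight_table` with `provenance = "supplied"`.
#' @examples
#' ct <- read_counting_dataset(relw_example("covid_ct_weights.csv"))
#' wt <- load_supplied_weights(ct)
#' wt$total      # 1.032
#' wt$normalized # FALSE
#' @export
load_supplied_weights <- function(dataset) {
  stopifnot(inherits(dataset, "counting_dataset"))
  pct <- dataset$variables$weight_pct
  missing <- is.na(pct)
  if (any(missing)) {
    abort_validation(sprintf(
      "Cannot load supplied weights: no `weight_pct` for %s.",
      comma(dataset$variables$variable[missing])
    ))
  }
  out_of_range <- pct < 0 | pct > 100
  if (any(out_of_range)) {
    abort_validation(sprintf(
      "`weight_pct` must lie in [0, 100]; offending variable(s): %s.",
      comma(dataset$variables$variable[out_of_range])
    ))
  }
  new_weight_table(dataset, weights = pct / 100, provenance = "supplied")
}

new_weight_table <- function(dataset, weights, provenance,
                             display_precision = 1L) {
  vars <- variable_names(dataset)
  total <- sum(weights)
  structure(
    list(
      dataset_name = dataset$name,
      variables = vars,
      weights = stats::setNames(as.numeric(weights), vars),
      provenance = provenance,
      total = total,
      normalized = total >= 0.995 && total <= 1.005,
      display_precision = as.integer(display_precision)
    ),
    class = "weight_table"
  )
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf(
    "<weight_table> %s (%s): %d variables, sum %s%s\n",
    x$dataset_name, x$provenance, length(x$weights),
    render_percent(x$total, x$display_precision),
    if (x$normalized) "" else " [not normalized]"
  ))
  print(as_weight_tibble(x), ...)
  invisible(x)
}

as_weight_tibble <- function(x) {
  tibble::tibble(
    variable = x$variables,
    weight = unname(x$weights[x$variables]),
    weight_pct = unname(vapply(x$weights[x$variables], render_percent,
                               character(1), precision = x$display_precision))
  )
}

#' Render a fraction as a percent string
#'
#' Display-only formatting; all internal arithmetic keeps full precision.
#' `"half_up"` rounds halves away from zero at the given number of decimal
#' places (the convention that reproduces the published weight tables —
#' base R's `round()` uses round-half-even and cannot); `"truncate"` drops
#' the excess digits. `compact = TRUE` drops trailing zero decimals, as the
#' published enumeration tables print `100` and `0`.
#'
#' @param fraction Numeric fraction(s); `0.165` renders as `"16.5%"`.
#' @param precision Decimal places (default 1).
#' @param mode `"half_up"` or `"truncate"`.
#' @param compact Drop trailing `".0"`?
#' @return Character vector of percent strings.
#' @examples
#' render_percent(46 / 279)            # "16.5%"
#' render_percent(18 / 279)            # "6.5%" (6.4516 rounds up)
#' render_percent(1, compact = TRUE)   # "100%"
#' @export
render_percent <- function(fraction, precision = 1,
                           mode = c("half_up", "truncate"),
                           compact = FALSE) {
  mode <- match.arg(mode)
  if (any(!is.finite(fraction))) {
    abort_validation("`fraction` must be finite.")
  }
  value <- percent_value(fraction, precision, mode)
  out <- formatC(value, format = "f", digits = precision)
  if (compact) {
    out <- sub("(\\.\\d*?)0+$", "\\1", out)
    out <- sub("\\.$", "", out)
  }
  paste0(out, "%")
}

#' @rdname render_percent
#' @return `percent_value()` returns the rounded percent as a number
#'   (`0.165` -> `16.5`), the form used in exported explanation tables.
#' @export
percent_value <- function(fraction, precision = 1,
                          mode = c("half_up", "truncate")) {
  mode <- match.arg(mode)
  scaled <- fraction * 100 * 10^precision
  # absolute tolerance absorbs representation error (e.g. 164.999999999997)
  eps <- 1e-9
  digits <- switch(mode,
    half_up = sign(scaled) * floor(abs(scaled) + 0.5 + eps),
    truncate = sign(scaled) * floor(abs(scaled) + eps)
  )
  digits / 10^precision
}
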