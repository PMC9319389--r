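#' Score a presence profile into positive and negative likelihood values
#'
#' The additive score at the heart of the model. In `sum_present` mode (the
#' default, matching the published worked examples) the positive likelihood
#' value is the sum of the present variables' relative weights,
#' \deqn{+LR = \sum_{v\ \mathrm{present}} w_v,}
#' and the negative value is its complement, \eqn{-LR = 1 - (+LR)}, always
#' exactly. `complement` mode computes \eqn{+LR = 1 - \sum_{v\
#' \mathrm{absent}} w_v} instead; the two coincide whenever the weight table
#' sums to 1, and differ by the normalization defect otherwise (the bundled
#' CT table sums to 103.2%, and some of its published near-all-present rows
#' are only reproducible in complement mode).
#'
#' Despite the field-standard "+LR/−LR" labels, these are additive scores in
#' `[0, 1]` (for normalized tables), not sensitivity/specificity-based
#' likelihood ratios. With a non-normalized supplied table the positive
#' score can leave `[0, 1]`; it is not clamped — a warning is attached and
#' emitted so the defect stays visible.
#'
#' @param profile A [presence_profile()] over the same variables as
#'   `weights`.
#' @param weights A `weight_table` from [relative_weights()] or
#'   [load_supplied_weights()].
#' @param mode `"sum_present"` (default) or `"complement"`.
#' @return A `score_result`: `positive_lr`, `negative_lr` (fractions),
#'   `contributions` (a tibble of variable, status, weight — present
#'   variables first, in decreasing weight order), `mode`, `warnings`.
#' @examples
#' ct <- read_counting_dataset(relw_example("covid_ct_weights.csv"))
#' wt <- load_supplied_weights(ct)
#' prof <- presence_profile(ct, present = c(
#'   "GGO", "Bronchiectasis", "Pericardial effusion",
#'   "Consolidation", "Bilateral multilobe", "Peripheral"
#' ))
#' res <- score_profile(prof, wt)
#' render_percent(res$positive_lr)  # "59.2%"
#' @export
score_profile <- function(profile, weights,
                          mode = c("sum_present", "complement")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "presence_profile"),
            inherits(weights, "weight_table"))
  if (!identical(profile$variables, weights$variables)) {
    abort_mismatch(sprintf(
      "Profile (dataset %s) and weight table (dataset %s) cover different variables.",
      encodeString(profile$dataset_name, quote = '"'),
      encodeString(weights$dataset_name, quote = '"')
    ))
  }
  w <- weights$weights[profile$variables]
  present <- profile$present[profile$variables]
  positive <- if (mode == "sum_present") {
    sum(w[present])
  } else {
    1 - sum(w[!present])
  }
  negative <- 1 - positive

  warnings <- character()
  if (positive < 0 || positive > 1) {
    warnings <- sprintf(
      "Positive score %s falls outside [0, 1]: the weight table sums to %s, not 100%%.",
      render_percent(positive, 1), render_percent(weights$total, 1)
    )
    rlang::warn(warnings, class = "relw_score_out_of_range")
  }

  ord <- order(!present, -w, seq_along(w))
  contributions <- tibble::tibble(
    variable = profile$variables[ord],
    status = ifelse(unname(present[ord]), "present", "absent"),
    weight = unname(w[ord])
  )
  structure(
    list(
      positive_lr = positive,
      negative_lr = negative,
      contributions = contributions,
      mode = mode,
      warnings = warnings,
      display_precision = weights$display_precision
    ),
    class = "score_result"
  )
}

#' @export
print.score_result <- function(x, ...) {
  p <- x$display_precision
  cat(sprintf(
    "<score_result> +LR %s / -LR %s (%s mode)\n",
    render_percent(x$positive_lr, p), render_percent(x$negative_lr, p), x$mode
  ))
  for (w in x$warnings) cat(" warning:", w, "\n")
  invisible(x)
}

#' Ranked explanation of a score
#'
#' Turns a [score_profile()] result into the clinician-facing report: each
#' present variable with its weight percent and the running cumulative
#' positive score, top contributor first, followed by the absent variables.
#' The last cumulative value equals the profile's positive score (in
#' `sum_present` mode).
#'
#' @param result A `score_result`.
#' @return A `score_explanation`: a tibble with columns `rank`, `variable`,
#'   `status`, `weight_pct`, `cumulative_pct` (cumulative over present
#'   variables only; `NA` for absent rows), plus the scores as attributes.
#'   Its print method renders the report.
#' @examples
#' ct <- read_counting_dataset(relw_example("covid_ct_weights.csv"))
#' wt <- load_supplied_weights(ct)
#' res <- score_profile(presence_profile(ct, "GGO"), wt)
#' explain(res)
#' @export
explain <- function(result) {
  stopifnot(inherits(result, "score_result"))
  contrib <- result$contributions
  present <- contrib$status == "present"
  cumulative <- rep(NA_real_, nrow(contrib))
  cumulative[present] <- cumsum(contrib$weight[present])
  p <- result$display_precision
  tab <- tibble::tibble(
    rank = seq_len(nrow(contrib)),
    variable = contrib$variable,
    status = contrib$status,
    weight_pct = percent_value(contrib$weight, p),
    cumulative_pct = ifelse(present, percent_value(cumulative, p), NA_real_)
  )
  structure(tab,
    class = c("score_explanation", class(tab)),
    positive_lr = result$positive_lr,
    negative_lr = result$negative_lr,
    mode = result$mode,
    display_precision = p
  )
}

#' @export
print.score_explanation <- function(x, ...) {
  p <- attr(x, "display_precision")
  cat(sprintf(
    "Explanation (%s mode): +LR %s, -LR %s\n",
    attr(x, "mode"),
    render_percent(attr(x, "positive_lr"), p),
    render_percent(attr(x, "negative_lr"), p)
  ))
  present <- x[x$status == "present", ]
  if (nrow(present) == 0) {
    cat("No variables present.\n")
  } else {
    for (i in seq_len(nrow(present))) {
      cat(sprintf(
        "  %2d. %-40s %6s%%  (cumulative %s%%)\n",
        i, present$variable[i],
        formatC(present$weight_pct[i], format = "f", digits = p),
        formatC(present$cumulative_pct[i], format = "f", digits = p)
      ))
    }
  }
  absent <- x$variable[x$status == "absent"]
  if (length(absent) > 0) {
    cat(" absent:", paste(absent, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sum weights over a list of table entries (with repeats allowed)
#'
#' Reproduces hand arithmetic over a weight table: sums the weights of the
#' named entries in the order given, allowing a name to appear more than
#' once. This is distinct from [score_profile()], where each variable
#' contributes at most once; it exists to audit published addend lists,
#' which occasionally repeat an entry.
#'
#' @param weights A `weight_table`.
#' @param names Character vector of variable names, repeats allowed.
#' @return The sum of the named weights, as a fraction.
#' @examples
#' wt <- load_supplied_weights(
#'   read_counting_dataset(relw_example("covid_symptom_weights.csv"))
#' )
#' sum_weights(wt, c("Dry Cough", "Headache"))
#' @export
sum_weights <- function(weights, names) {
  stopifnot(inherits(weights, "weight_table"))
  unknown <- setdiff(unique(names), weights$variables)
  if (length(unknown) > 0) {
    abort_validation(sprintf("Unknown variable name(s): %s.", comma(unknown)))
  }
  sum(weights$weights[names])
}
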