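#' Specify a synthetic counting dataset
#'
#' The generator emulates the structure of a real symptom/imaging cohort so
#' every other module can be property-tested on data it did not see: `k`
#' binary variables, optional exclusive groups (like fever grades), per
#' variable a patient count drawn under one of two laws, and per-variable
#' prevalences for sampling patient profiles. Defaults mirror the bundled
#' cohort: 15 variables, 112 patients, counts as concentration-1 proportions
#' of a fixed total of 279.
#'
#' A single integer seed governs all randomness; generation is scoped with
#' [withr::with_seed()] so repeated calls with the same spec are identical
#' and the caller's RNG state is untouched.
#'
#' @param n_variables Number of variables (k >= 1).
#' @param total_patients Cohort size.
#' @param count_law `"proportions"`: counts are a multinomial draw of
#'   `count_total` over Dirichlet(`concentration`) proportions;
#'   `"uniform"`: counts are independent uniform integers in `count_range`.
#' @param count_total Total count mass under `"proportions"`.
#' @param concentration Dirichlet concentration; 1 is flat, larger is more
#'   even, smaller is spikier (a few dominant variables, like a real
#'   symptom table).
#' @param count_range Inclusive integer range under `"uniform"`.
#' @param groups Optional character vector of length `n_variables` assigning
#'   group labels (`NA` = ungrouped).
#' @param prevalence Optional per-variable presence probabilities in
#'   `[0, 1]` for [sample_profiles()]; defaults there to `count /
#'   total_patients` capped at 1.
#' @param seed Integer seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_variables = 15,
                           total_patients = 112,
                           count_law = c("proportions", "uniform"),
                           count_total = 279,
                           concentration = 1,
                           count_range = c(0, total_patients),
                           groups = NULL,
                           prevalence = NULL,
                           seed = 1L) {
  count_law <- match.arg(count_law)
  n_variables <- assert_count_scalar(n_variables, "n_variables")
  stopifnot(n_variables >= 1)
  total_patients <- assert_count_scalar(total_patients, "total_patients")
  if (!is.null(groups) && length(groups) != n_variables) {
    abort_validation("`groups` must have one label per variable.")
  }
  if (!is.null(prevalence)) {
    stopifnot(length(prevalence) == n_variables,
              all(prevalence >= 0 & prevalence <= 1))
  }
  structure(
    list(
      n_variables = n_variables, total_patients = total_patients,
      count_law = count_law, count_total = count_total,
      concentration = concentration, count_range = as.integer(count_range),
      groups = groups, prevalence = prevalence,
      seed = assert_count_scalar(seed, "seed")
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic counting dataset
#'
#' @param spec A [synthetic_spec()].
#' @return A validated [counting_dataset()] named `"synthetic"`, with
#'   variables `V01, V02, ...`. Deterministic in `spec$seed`.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_variables = 6, seed = 7))
#' sum(relative_weights(ds)$weights)  # 1
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$n_variables
  counts <- withr::with_seed(spec$seed, {
    if (spec$count_law == "proportions") {
      gamma <- stats::rgamma(k, shape = spec$concentration, rate = 1)
      if (sum(gamma) == 0) gamma <- rep(1, k)
      drop(stats::rmultinom(1, size = spec$count_total, prob = gamma / sum(gamma)))
    } else {
      spec$count_range[1] +
        floor(stats::runif(k) * (diff(spec$count_range) + 1L))
    }
  })
  # a dataset of all-zero counts is valid I/O but degenerate for weighting;
  # keep at least one positive count so downstream properties are testable
  if (sum(counts) == 0) counts[1] <- 1
  counting_dataset(
    tibble::tibble(
      variable = sprintf("V%02d", seq_len(k)),
      group = if (is.null(spec$groups)) NA_character_ else spec$groups,
      count = as.numeric(counts)
    ),
    total_patients = max(spec$total_patients, max(counts)),
    name = "synthetic"
  )
}

#' Sample synthetic patient profiles
#'
#' Draws `n_patients` presence profiles with independent per-variable
#' Bernoulli presence at the stated prevalences, so empirical prevalence
#' converges to the stated one as `n_patients` grows.
#'
#' @param dataset A [counting_dataset()].
#' @param prevalence Per-variable presence probabilities (recycled if
#'   scalar). Defaults to `count / total_patients` when the dataset carries
#'   counts and a cohort size.
#' @param n_patients Number of profiles to draw.
#' @param seed Integer seed (independent of [generate_dataset()]'s).
#' @return A list of [presence_profile()] objects.
#' @export
sample_profiles <- function(dataset, prevalence = NULL, n_patients, seed = 1L) {
  stopifnot(inherits(dataset, "counting_dataset"))
  k <- n_variables(dataset)
  if (is.null(prevalence)) {
    if (any(is.na(dataset$variables$count)) || is.null(dataset$total_patients)) {
      abort_validation(
        "No `prevalence` given and the dataset lacks counts or a cohort size."
      )
    }
    prevalence <- pmin(dataset$variables$count / dataset$total_patients, 1)
  }
  if (length(prevalence) == 1) prevalence <- rep(prevalence, k)
  stopifnot(length(prevalence) == k,
            all(prevalence >= 0 & prevalence <= 1))
  vars <- variable_names(dataset)
  withr::with_seed(assert_count_scalar(seed, "seed"), {
    lapply(seq_len(n_patients), function(i) {
      present <- vars[stats::runif(k) < prevalence]
      presence_profile(dataset, present = present)
    })
  })
}
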