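#' Construct a counting dataset
#'
#' A counting dataset is the training input of the relative-weight model: one
#' row per binary diagnostic variable (a symptom such as "Dry Cough" or an
#' imaging finding such as "GGO"), carrying the number of patients in the
#' cohort who exhibit it and/or a pre-tabulated weight in percent. Row order
#' is significant and is preserved through every downstream output, including
#' the column order of enumeration tables.
#'
#' Each variable must carry at least one of: a `count`, a `weight_pct`, or a
#' complete (`weight_min_pct`, `weight_max_pct`) pair of bounds. Variable
#' names are matched exactly (case-sensitive, no normalization): clinical
#' labels routinely embed parenthesized ranges such as
#' `"Low-grade fever (37.3-38.0)"` that must not be folded.
#'
#' Groups mark mutually related categorical families (e.g. the fever grades,
#' or the distribution of pulmonary lesions). By default they are metadata
#' only: enumeration deliberately includes clinically contradictory
#' combinations, because the exhaustive explanation table covers every
#' profile. `strict_groups = TRUE` (in [score_profile()] / [read_profile()])
#' opts into enforcing at most one present variable per group.
#'
#' @param variables A data frame with a `variable` column (unique, non-empty
#'   character) and any of `group`, `count`, `weight_pct`, `weight_min_pct`,
#'   `weight_max_pct`. Missing columns are filled with `NA`.
#' @param total_patients Optional positive integer: the cohort size (e.g. 112
#'   confirmed patients). Required for [prevalence_weight()].
#' @param source_kind `"symptoms"` or `"image_features"`. Labels which family
#'   of algorithm the dataset feeds; the computation is identical.
#' @param name Dataset name used in reports and mismatch checks.
#' @return An object of class `counting_dataset`.
#' @examples
#' ds <- counting_dataset(
#'   data.frame(variable = c("Dry Cough", "Fatigue"), count = c(48, 38)),
#'   total_patients = 112, name = "mini"
#' )
#' relative_weights(ds)
#' @export
counting_dataset <- function(variables,
                             total_patients = NULL,
                             source_kind = c("symptoms", "image_features"),
                             name = "dataset") {
  source_kind <- match.arg(source_kind)
  variables <- as_variable_table(variables)
  validate_variable_table(variables)
  if (!is.null(total_patients)) {
    total_patients <- assert_count_scalar(total_patients, "total_patients")
    if (total_patients < 1L) {
      abort_validation("`total_patients` must be a positive integer.")
    }
    over <- !is.na(variables$count) & variables$count > total_patients
    if (any(over)) {
      abort_validation(sprintf(
        "Count exceeds `total_patients` (%d) for: %s.",
        total_patients, comma(variables$variable[over])
      ))
    }
  }
  structure(
    list(
      variables = variables,
      total_patients = total_patients,
      source_kind = source_kind,
      name = as.character(name)[1]
    ),
    class = "counting_dataset"
  )
}

# Coerce any input data frame to the canonical column set, preserving order.
as_variable_table <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"variable" %in% names(df)) {
    abort_validation("Dataset must have a `variable` column.")
  }
  cols <- c("variable", "group", "count", "weight_pct",
            "weight_min_pct", "weight_max_pct")
  for (col in setdiff(cols, names(df))) {
    df[[col]] <- if (col == "group") NA_character_ else NA_real_
  }
  df$variable <- as.character(df$variable)
  df$group <- as.character(df$group)
  df$group[!is.na(df$group) & df$group == ""] <- NA_character_
  for (col in c("count", "weight_pct", "weight_min_pct", "weight_max_pct")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df[cols]
}

validate_variable_table <- function(df) {
  if (nrow(df) == 0) {
    abort_validation("Dataset has no variables.")
  }
  if (any(is.na(df$variable) | df$variable == "")) {
    abort_validation("Variable names must be non-empty.")
  }
  dup <- df$variable[duplicated(df$variable)]
  if (length(dup) > 0) {
    abort_validation(sprintf(
      "Duplicate variable name(s): %s. Names must be unique (case-sensitive).",
      comma(unique(dup))
    ))
  }
  bad_count <- !is.na(df$count) & (df$count < 0 | df$count != floor(df$count))
  if (any(bad_count)) {
    abort_validation(sprintf(
      "Counts must be non-negative integers; offending variable(s): %s.",
      comma(df$variable[bad_count])
    ))
  }
  for (col in c("weight_pct", "weight_min_pct", "weight_max_pct")) {
    bad <- !is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 100)
    if (any(bad)) {
      abort_validation(sprintf(
        "`%s` must lie in [0, 100]; offending variable(s): %s.",
        col, comma(df$variable[bad])
      ))
    }
  }
  half_bounds <- xor(is.na(df$weight_min_pct), is.na(df$weight_max_pct))
  if (any(half_bounds)) {
    abort_validation(sprintf(
      "Weight bounds must be given as a min/max pair; incomplete for: %s.",
      comma(df$variable[half_bounds])
    ))
  }
  inverted <- !is.na(df$weight_min_pct) & df$weight_min_pct > df$weight_max_pct
  if (any(inverted)) {
    abort_validation(sprintf(
      "`weight_min_pct` exceeds `weight_max_pct` for: %s.",
      comma(df$variable[inverted])
    ))
  }
  none <- is.na(df$count) & is.na(df$weight_pct) & is.na(df$weight_min_pct)
  if (any(none)) {
    abort_validation(sprintf(
      "Each variable needs a count, a weight, or weight bounds; missing for: %s.",
      comma(df$variable[none])
    ))
  }
  invisible(df)
}

#' @export
print.counting_dataset <- function(x, ...) {
  cat(sprintf(
    "<counting_dataset> %s (%s): %d variables%s\n",
    x$name, x$source_kind, nrow(x$variables),
    if (is.null(x$total_patients)) ""
    else sprintf(", %d patients", x$total_patients)
  ))
  print(x$variables, ...)
  invisible(x)
}

#' Number and names of dataset variables
#'
#' @param dataset A [counting_dataset()].
#' @return `variable_names()` returns the variable labels in dataset order;
#'   `n_variables()` returns their number.
#' @export
variable_names <- function(dataset) {
  stopifnot(inherits(dataset, "counting_dataset"))
  dataset$variables$variable
}

#' @rdname variable_names
#' @export
n_variables <- function(dataset) length(variable_names(dataset))

#' Construct a presence/absence profile over a dataset's variables
#'
#' A profile assigns present (`+`) or absent (`-`) to every variable of a
#' dataset — one row of the exhaustive explanation table. Variables named in
#' `present` are marked present; all others absent.
#'
#' @param dataset A [counting_dataset()].
#' @param present Character vector of present variable names (may be empty).
#'   Names must match dataset variables exactly.
#' @param strict_groups If `TRUE`, reject profiles with more than one present
#'   variable in the same group (e.g. two fever grades at once).
#' @return An object of class `presence_profile`.
#' @examples
#' ds <- counting_dataset(
#'   data.frame(variable = c("Dry Cough", "Fatigue"), count = c(48, 38))
#' )
#' presence_profile(ds, present = "Dry Cough")
#' @export
presence_profile <- function(dataset, present = character(),
                             strict_groups = FALSE) {
  stopifnot(inherits(dataset, "counting_dataset"))
  vars <- variable_names(dataset)
  present <- as.character(present)
  unknown <- setdiff(unique(present), vars)
  if (length(unknown) > 0) {
    hints <- vapply(unknown, near_matches, character(1), candidates = vars)
    abort_validation(paste0(
      "Unknown variable name(s): ",
      paste0(sprintf("%s%s", encodeString(unknown, quote = '"'), hints),
             collapse = "; "),
      "."
    ))
  }
  status <- stats::setNames(vars %in% present, vars)
  if (strict_groups) {
    grp <- dataset$variables$group
    tab <- table(grp[status & !is.na(grp)])
    clash <- names(tab)[tab > 1]
    if (length(clash) > 0) {
      abort_validation(sprintf(
        "More than one present variable in group(s): %s (strict group mode).",
        comma(clash)
      ))
    }
  }
  structure(
    list(dataset_name = dataset$name, variables = vars, present = status),
    class = "presence_profile"
  )
}

near_matches <- function(x, candidates) {
  d <- utils::adist(x, candidates, ignore.case = TRUE)
  close <- candidates[d <= pmax(3, nchar(x) %/% 3)]
  if (length(close) == 0) return("")
  sprintf(" (did you mean %s?)", comma(encodeString(utils::head(close, 3), quote = '"')))
}

#' @export
print.presence_profile <- function(x, ...) {
  n_present <- sum(x$present)
  cat(sprintf(
    "<presence_profile> %s: %d present / %d absent\n",
    x$dataset_name, n_present, length(x$present) - n_present
  ))
  if (n_present > 0) {
    cat(" present:", paste(names(x$present)[x$present], collapse = ", "), "\n")
  }
  invisible(x)
}

comma <- function(x) paste(x, collapse = ", ")

assert_count_scalar <- function(x, what) {
  if (length(x) != 1 || is.na(x) || !is.numeric(x) || x != floor(x)) {
    abort_validation(sprintf("`%s` must be a single integer.", what))
  }
  as.integer(x)
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = c("relw_validation_error", "relw_error"))
}

abort_format <- function(msg) {
  rlang::abort(msg, class = c("relw_format_error", "relw_error"))
}

abort_mismatch <- function(msg) {
  rlang::abort(msg, class = c("relw_mismatch_error", "relw_error"))
}
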