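#' Build a run configuration
#'
#' A fully serializable description of one pipeline run, so any run is
#' reconstructible from its logged config. Configs round-trip through JSON
#' or YAML via [read_run_config()] / [write_run_config()].
#'
#' @param action One of `"validate"`, `"weights"`, `"score"`, `"enumerate"`,
#'   `"synth"`.
#' @param dataset Path to the counting dataset.
#' @param weights_from `"counts"` (compute via [relative_weights()]) or
#'   `"supplied"` (load `weight_pct` via [load_supplied_weights()]).
#' @param present Character vector of present variable names (for
#'   `"score"`), or a profile file path in `profile`.
#' @param profile Optional profile file path.
#' @param mode Scoring mode.
#' @param order Enumeration row order.
#' @param top Optional row cap for `"enumerate"` (uses [top_profiles()]).
#' @param precision Display precision for percents.
#' @param output Optional output file path.
#' @param strict_groups Enforce one present variable per group.
#' @param n,total,seed Synthetic-generation parameters (for `"synth"`).
#' @return A `run_config`.
#' @export
run_config <- function(action = c("validate", "weights", "score",
                                  "enumerate", "synth"),
                       dataset = NULL,
                       weights_from = c("counts", "supplied"),
                       present = character(),
                       profile = NULL,
                       mode = c("sum_present", "complement"),
                       order = c("binary", "by_lr_desc"),
                       top = NULL,
                       precision = 1L,
                       output = NULL,
                       strict_groups = FALSE,
                       n = 15L, total = 112L, seed = 1L) {
  structure(
    list(
      action = match.arg(action),
      dataset = dataset,
      weights_from = match.arg(weights_from),
      present = as.character(present),
      profile = profile,
      mode = match.arg(mode),
      order = match.arg(order),
      top = top,
      precision = as.integer(precision),
      output = output,
      strict_groups = isTRUE(strict_groups),
      n = as.integer(n), total = as.integer(total), seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path Config file (`.json`, `.yaml`/`.yml`).
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- config[!vapply(config, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(payload, path)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Execute a configured pipeline run
#'
#' The end-to-end driver behind the command-line interface: read and
#' validate the dataset, derive or load the weight table, then score,
#' enumerate, or generate, writing any requested output files. All log
#' lines (dataset summary, weight-table sum, scoring warnings) go through
#' `message()` (stderr); data goes to `config$output` or the returned
#' object. Identical inputs and config produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress log messages.
#' @return A list with class `run_result`: `config`, `status` (0 on
#'   success), and an action-dependent `value` (dataset, weight tibble,
#'   [explain()] report, explanation tibble, or synthetic dataset).
#'   Validation failures raise classed conditions (`relw_error`); the CLI
#'   maps them to a non-zero exit.
#' @examples
#' cfg <- run_config(
#'   action = "score",
#'   dataset = relw_example("covid_symptom_counts.csv"),
#'   present = c("Dry Cough", "Headache")
#' )
#' res <- run_pipeline(cfg, quiet = TRUE)
#' res$value
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(...) if (!quiet) message(sprintf(...))

  if (config$action == "synth") {
    spec <- synthetic_spec(n_variables = config$n, total_patients = config$total,
                           seed = config$seed)
    ds <- generate_dataset(spec)
    log_msg("Generated synthetic dataset: %d variables, seed %d.",
            n_variables(ds), config$seed)
    if (!is.null(config$output)) write_counting_dataset(ds, config$output)
    return(run_result(config, ds))
  }

  if (is.null(config$dataset)) {
    abort_validation("`dataset` is required for this action.")
  }
  ds <- read_counting_dataset(config$dataset)
  log_msg("Dataset %s: %d variables%s.", ds$name, n_variables(ds),
          if (is.null(ds$total_patients)) ""
          else sprintf(", %d patients", ds$total_patients))

  if (config$action == "validate") {
    return(run_result(config, ds))
  }

  wt <- if (config$weights_from == "counts") {
    relative_weights(ds)
  } else {
    load_supplied_weights(ds)
  }
  wt$display_precision <- config$precision
  log_msg("Weight table (%s): sum %s%s.", wt$provenance,
          render_percent(wt$total, config$precision),
          if (wt$normalized) "" else " [not normalized]")

  value <- switch(config$action,
    weights = as_weight_tibble(wt),
    score = {
      tokens <- if (!is.null(config$profile)) config$profile else config$present
      prof <- read_profile(tokens, ds, strict_groups = config$strict_groups)
      res <- withCallingHandlers(
        score_profile(prof, wt, mode = config$mode),
        relw_score_out_of_range = function(w) {
          log_msg("warning: %s", conditionMessage(w))
          rlang::cnd_muffle(w)
        }
      )
      explain(res)
    },
    enumerate = {
      if (!is.null(config$top)) {
        top_profiles(wt, mode = config$mode, k_rows = config$top)
      } else {
        et <- enumerate_profiles(wt, mode = config$mode, order = config$order)
        if (!is.null(config$output)) {
          write_explanations(et, config$output)
          log_msg("Wrote %s rows to %s.",
                  format(et$total_rows, big.mark = ","), config$output)
          et
        } else {
          collect_explanations(et)
        }
      }
    }
  )
  if (!is.null(config$output) && is.data.frame(value)) {
    write_table(value, config$output)
    log_msg("Wrote %s.", config$output)
  }
  run_result(config, value)
}

run_result <- function(config, value) {
  structure(list(config = config, status = 0L, value = value),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> action %s, status %d\n", x$config$action, x$status))
  print(x$value, ...)
  invisible(x)
}
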