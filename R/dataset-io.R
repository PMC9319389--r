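#' Read a counting dataset from CSV, TSV, or JSON
#'
#' The tabular dialects (CSV, TSV; RFC-4180 quoting) use the column schema
#' `variable,group,count,weight_pct,weight_min_pct,weight_max_pct` with blank
#' cells meaning absent. Dataset-level metadata travels in front-matter
#' comment lines before the header, e.g.:
#'
#' ```
#' #name: covid_symptoms
#' #source_kind: symptoms
#' #total_patients: 112
#' variable,group,count
#' Low-grade fever (37.3-38.0),fever,46
#' ...
#' ```
#'
#' The JSON dialect carries the same fields natively:
#' `{"name": ..., "source_kind": ..., "total_patients": ..., "variables": [...]}`.
#' Row order is preserved exactly; see [counting_dataset()] for the
#' validation rules applied after parsing.
#'
#' @param path Path to the file.
#' @param dialect `"csv"`, `"tsv"`, or `"json"`. Defaults to the file
#'   extension.
#' @return A validated [counting_dataset()].
#' @seealso [write_counting_dataset()] for the inverse; round-trips are
#'   lossless in every dialect.
#' @examples
#' path <- relw_example("covid_symptom_counts.csv")
#' ds <- read_counting_dataset(path)
#' n_variables(ds)
#' @export
read_counting_dataset <- function(path, dialect = NULL) {
  dialect <- resolve_dialect(dialect, path)
  if (!file.exists(path)) {
    abort_format(sprintf("File not found: %s", path))
  }
  if (dialect == "json") {
    parsed <- tryCatch(
      jsonlite::read_json(path, simplifyVector = TRUE),
      error = function(e) abort_format(sprintf(
        "Failed to parse %s as JSON: %s", path, conditionMessage(e)
      ))
    )
    if (!is.list(parsed) || is.null(parsed$variables)) {
      abort_format(sprintf("JSON dataset %s lacks a `variables` array.", path))
    }
    vars <- tibble::as_tibble(parsed$variables)
    return(counting_dataset(
      vars,
      total_patients = parsed$total_patients,
      source_kind = parsed$source_kind %||% "symptoms",
      name = parsed$name %||% dataset_name_from_path(path)
    ))
  }

  meta <- read_front_matter(path)
  delim <- if (dialect == "tsv") "\t" else ","
  body <- tryCatch(
    readr::read_delim(
      path, delim = delim, comment = "#",
      col_types = readr::cols(.default = readr::col_guess()),
      progress = FALSE, show_col_types = FALSE
    ),
    error = function(e) abort_format(sprintf(
      "Failed to parse %s as %s: %s", path, dialect, conditionMessage(e)
    ))
  )
  problems <- readr::problems(body)
  if (nrow(problems) > 0) {
    abort_format(sprintf(
      "Malformed %s in %s at line %d: %s.",
      dialect, path, problems$row[1] + 1L, problems$expected[1]
    ))
  }
  if (nrow(body) == 0 || ncol(body) == 0) {
    abort_format(sprintf("Dataset file %s is empty.", path))
  }
  counting_dataset(
    body,
    total_patients = meta$total_patients,
    source_kind = meta$source_kind %||% "symptoms",
    name = meta$name %||% dataset_name_from_path(path)
  )
}

#' Write a counting dataset (or any relw table) to disk
#'
#' `write_counting_dataset()` emits the front-matter + columns layout that
#' [read_counting_dataset()] reads back, dropping all-`NA` optional columns;
#' `read(write(x))` reproduces `x` exactly. `write_table()` writes a plain
#' data frame (a weight table export, an explanation-table slice) without
#' front matter.
#'
#' @param dataset A [counting_dataset()].
#' @param path Output path.
#' @param dialect `"csv"`, `"tsv"`, or `"json"`; defaults to the extension.
#' @return `path`, invisibly.
#' @export
write_counting_dataset <- function(dataset, path, dialect = NULL) {
  stopifnot(inherits(dataset, "counting_dataset"))
  dialect <- resolve_dialect(dialect, path)
  if (dialect == "json") {
    vars <- drop_empty_columns(dataset$variables)
    payload <- list(
      name = dataset$name,
      source_kind = dataset$source_kind,
      total_patients = dataset$total_patients,
      variables = vars
    )
    payload <- payload[!vapply(payload, is.null, logical(1))]
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    return(invisible(path))
  }
  header <- c(
    sprintf("#name: %s", dataset$name),
    sprintf("#source_kind: %s", dataset$source_kind),
    if (!is.null(dataset$total_patients)) {
      sprintf("#total_patients: %d", dataset$total_patients)
    }
  )
  writeLines(header, path, useBytes = TRUE)
  body <- drop_empty_columns(dataset$variables)
  readr::write_delim(body, path, delim = if (dialect == "tsv") "\t" else ",",
                     na = "", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_counting_dataset
#' @param x A data frame.
#' @export
write_table <- function(x, path, dialect = NULL) {
  dialect <- resolve_dialect(dialect, path)
  if (dialect == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else if (dialect == "tsv") {
    readr::write_tsv(tibble::as_tibble(x), path, na = "")
  } else {
    readr::write_csv(tibble::as_tibble(x), path, na = "")
  }
  invisible(path)
}

#' Read a presence profile
#'
#' Accepts either a character vector of present-variable names (CLI-token
#' style) or a path to a file: a two-column `variable,status` CSV/TSV with
#' status in `+`/`-` (or `present`/`absent`), or a plain list of present
#' names, one per line. Variables not mentioned are absent.
#'
#' @param path_or_tokens File path, or character vector of present names.
#' @param dataset The [counting_dataset()] the profile refers to.
#' @param strict_groups Passed to [presence_profile()].
#' @return A [presence_profile()].
#' @export
read_profile <- function(path_or_tokens, dataset, strict_groups = FALSE) {
  stopifnot(inherits(dataset, "counting_dataset"))
  tokens <- path_or_tokens
  if (length(tokens) == 1 && !is.na(tokens) && file.exists(tokens)) {
    tokens <- parse_profile_file(tokens)
  }
  presence_profile(dataset, present = tokens, strict_groups = strict_groups)
}

parse_profile_file <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0) return(character())
  delim <- if (any(grepl("\t", lines))) "\t" else ","
  first <- strsplit(lines[1], delim, fixed = TRUE)[[1]]
  if (length(first) >= 2 && tolower(trimws(first[1])) == "variable") {
    tab <- readr::read_delim(path, delim = delim, comment = "#",
                             show_col_types = FALSE, progress = FALSE)
    status <- tolower(trimws(as.character(tab$status)))
    present <- status %in% c("+", "present", "true", "1", "yes")
    return(as.character(tab$variable)[present])
  }
  # plain list of present names, one per line
  lines
}

#' Write a presence profile as a two-column table
#'
#' @param profile A [presence_profile()].
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`; defaults to the extension.
#' @export
write_profile <- function(profile, path, dialect = NULL) {
  stopifnot(inherits(profile, "presence_profile"))
  dialect <- resolve_dialect(dialect, path, allow_json = FALSE)
  tab <- tibble::tibble(
    variable = profile$variables,
    status = ifelse(profile$present[profile$variables], "+", "-")
  )
  write_table(tab, path, dialect)
}

#' Path to a bundled example dataset
#'
#' The package ships the reference tables of a 112-patient COVID-19 cohort
#' as plain-text fixtures:
#' `covid_symptom_counts.csv` (15 symptom variables with patient counts),
#' `covid_symptom_weights.csv` (their published relative weights, summing to
#' 100.0%), `covid_ct_weights.csv` (19 chest-CT variables with published
#' relative weights, summing to 103.2%), and `covid_ct_bounds.csv` (the CT
#' variables with min/max prevalence-weight bounds).
#'
#' @param file Fixture file name; omit to list available fixtures.
#' @return A file path, or a character vector of fixture names.
#' @examples
#' relw_example()
#' read_counting_dataset(relw_example("covid_ct_weights.csv"))
#' @export
relw_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "relw")))
  }
  path <- system.file("extdata", file, package = "relw")
  if (path == "") {
    abort_format(sprintf("No bundled fixture named %s.", file))
  }
  path
}

resolve_dialect <- function(dialect, path, allow_json = TRUE) {
  choices <- c("csv", "tsv", if (allow_json) "json")
  if (is.null(dialect)) {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% choices) ext else "csv"
  }
  if (!dialect %in% choices) {
    abort_format(sprintf("Unsupported dialect %s (use %s).",
                         encodeString(dialect, quote = '"'), comma(choices)))
  }
  dialect
}

read_front_matter <- function(path) {
  meta <- list()
  con <- file(path, open = "rt", encoding = "UTF-8")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0 || !startsWith(line, "#")) break
    m <- regmatches(line, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", line))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  if (!is.null(meta$total_patients)) {
    meta$total_patients <- as.integer(meta$total_patients)
  }
  meta
}

dataset_name_from_path <- function(path) {
  tools::file_path_sans_ext(basename(path))
}

drop_empty_columns <- function(df) {
  keep <- vapply(df, function(col) !all(is.na(col)), logical(1))
  keep["variable"] <- TRUE
  df[keep]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
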