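# Shared fixtures: the bundled cohort tables plus small in-code datasets.

symptom_counts <- function() {
  read_counting_dataset(relw_example("covid_symptom_counts.csv"))
}

symptom_weights <- function() {
  load_supplied_weights(
    read_counting_dataset(relw_example("covid_symptom_weights.csv"))
  )
}

ct_weights_dataset <- function() {
  read_counting_dataset(relw_example("covid_ct_weights.csv"))
}

ct_weights <- function() load_supplied_weights(ct_weights_dataset())

# The six CT findings of the published neural-network worked example.
ct_example_present <- c(
  "GGO", "Bronchiectasis", "Pericardial effusion",
  "Consolidation", "Bilateral multilobe", "Peripheral"
)

tiny_dataset <- function(counts = c(3, 1, 6), names = NULL) {
  k <- length(counts)
  counting_dataset(
    tibble::tibble(
      variable = names %||% paste0("v", seq_len(k)),
      count = counts
    ),
    total_patients = max(sum(counts), 1),
    name = "tiny"
  )
}

# Independent oracle: score every one of the 2^k profiles by direct
# re-summation over a logical presence matrix (no package scoring code).
brute_force_rows <- function(weights_vec, mode = "sum_present") {
  k <- length(weights_vec)
  grid <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), k)))
  plr <- apply(grid, 1, function(present) {
    if (mode == "sum_present") sum(weights_vec[present])
    else 1 - sum(weights_vec[!present])
  })
  list(present = grid, positive_lr = plr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
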