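test_that("enumeration covers exactly 2^k distinct profiles", {
  ds <- read_counting_dataset(relw_example("covid_symptom_weights.csv"))
  et <- enumerate_profiles(symptom_weights())
  expect_equal(et$total_rows, 2^15)

  small <- relative_weights(tiny_dataset(c(2, 5, 1, 7)))
  rows <- collect_explanations(enumerate_profiles(small))
  expect_equal(nrow(rows), 16)
  keys <- apply(rows[, c("v1", "v2", "v3", "v4")], 1, paste, collapse = "")
  expect_equal(length(unique(keys)), 16)
  expect_equal(rows$explanation_number, as.numeric(1:16))
})

test_that("first and last rows are all-present and all-absent", {
  wt <- symptom_weights()
  et <- enumerate_profiles(wt)
  first <- collect_explanations(et, n = 1)
  expect_true(all(first[, wt$variables] == "+"))
  expect_equal(first$positive_lr_pct, 100)
  expect_equal(first$negative_lr_pct, 0)

  last <- lookup_profile(
    presence_profile(read_counting_dataset(relw_example("covid_symptom_weights.csv"))),
    wt
  )
  expect_equal(last$explanation_number, 2^15)
  expect_equal(last$positive_lr_pct, 0)
  expect_equal(last$negative_lr_pct, 100)
})

test_that("a single variable of weight w enumerates to rows {w, 0}", {
  one <- relative_weights(tiny_dataset(5, names = "only"))
  rows <- collect_explanations(enumerate_profiles(one))
  expect_equal(nrow(rows), 2)
  expect_equal(rows$positive_lr_pct, c(100, 0))
  expect_equal(rows$only, c("+", "-"))
})

test_that("positive and negative percent columns complement to 100", {
  ds <- generate_dataset(synthetic_spec(n_variables = 8, seed = 2))
  rows <- collect_explanations(enumerate_profiles(relative_weights(ds)))
  expect_true(all(abs(rows$positive_lr_pct + rows$negative_lr_pct - 100) <= 0.1))
})

test_that("enumerated rows match the brute-force oracle as a multiset", {
  ds <- generate_dataset(synthetic_spec(n_variables = 4, seed = 13))
  wt <- relative_weights(ds)
  rows <- collect_explanations(enumerate_profiles(wt))
  oracle <- brute_force_rows(unname(wt$weights))
  key <- function(mat) {
    apply(mat, 1, function(r) paste(ifelse(as.logical(r), "+", "-"), collapse = ""))
  }
  got <- sort(paste(key(rows[, variable_names(ds)] == "+"),
                    rows$positive_lr_pct))
  want <- sort(paste(key(oracle$present),
                     percent_value(oracle$positive_lr)))
  expect_equal(got, want)
})

test_that("lookup agrees with the enumerated row for random 19-variable profiles", {
  ct <- ct_weights_dataset()
  wt <- ct_weights()
  vars <- variable_names(ct)
  # draw random profiles, look each up in O(k), then stream the full
  # enumeration once and pick out the rows with matching ± patterns
  looked_up <- withr::with_seed(8, {
    lapply(1:200, function(i) {
      present <- vars[stats::runif(19) < 0.5]
      lookup_profile(presence_profile(ct, present), wt)
    })
  })
  looked_up <- do.call(rbind, looked_up)
  wanted <- do.call(paste0, looked_up[vars])
  found <- new.env()
  stream_explanations(enumerate_profiles(wt), function(chunk) {
    pattern <- do.call(paste0, chunk[vars])
    hit <- which(pattern %in% wanted)
    for (i in hit) {
      assign(pattern[i],
             c(chunk$explanation_number[i], chunk$positive_lr_pct[i],
               chunk$negative_lr_pct[i]),
             envir = found)
    }
  })
  for (i in seq_len(nrow(looked_up))) {
    expect_equal(
      unname(get(wanted[i], envir = found)),
      c(looked_up$explanation_number[i], looked_up$positive_lr_pct[i],
        looked_up$negative_lr_pct[i])
    )
  }
})

test_that("the published single-present and all-but-one rows reproduce by content", {
  sym_ds <- read_counting_dataset(relw_example("covid_symptom_weights.csv"))
  sym <- symptom_weights()
  only_moderate <- lookup_profile(
    presence_profile(sym_ds, "Moderate-grade fever (38.1-39.0)"), sym
  )
  expect_equal(only_moderate$positive_lr_pct, 11.1)
  expect_equal(only_moderate$negative_lr_pct, 88.9)

  ct <- ct_weights_dataset()
  cwt <- ct_weights()
  only_peripheral <- lookup_profile(presence_profile(ct, "Peripheral"), cwt)
  expect_equal(only_peripheral$positive_lr_pct, 13.1)

  all_but_peripheral <- lookup_profile(
    presence_profile(ct, setdiff(variable_names(ct), "Peripheral")),
    cwt, mode = "complement"
  )
  expect_equal(all_but_peripheral$positive_lr_pct, 86.9)
  expect_equal(all_but_peripheral$negative_lr_pct, 13.1)

  all_but_central <- lookup_profile(
    presence_profile(ct, setdiff(variable_names(ct), "Central")),
    cwt, mode = "complement"
  )
  expect_equal(all_but_central$positive_lr_pct, 99.7)
})

test_that("mean positive score over all rows is half the table total", {
  # each variable is present in exactly half the profiles
  for (seed in c(3, 17)) {
    ds <- generate_dataset(synthetic_spec(n_variables = 6, seed = seed))
    wt <- relative_weights(ds)
    et <- enumerate_profiles(wt)
    total <- 0
    n <- stream_explanations(et, function(chunk) {
      total <<- total + sum(chunk$positive_lr_pct)
    })
    expect_equal(total / n, 100 * wt$total / 2, tolerance = 0.05)
  }
})

test_that("top-k drops the smallest weights first with binary-order ties", {
  sym <- symptom_weights()
  top <- top_profiles(sym, k_rows = 3)
  expect_equal(top$positive_lr_pct, c(100, 99.3, 99.3))
  expect_equal(top$explanation_number[1], 1)
  # the two 99.3 rows drop one of the two smallest (0.7%) weights each,
  # lower explanation number first
  expect_true(all(diff(top$explanation_number) > 0))

  # exhaustive k_rows equals the full table, re-ordered by score
  small <- relative_weights(tiny_dataset(c(2, 5, 1, 7)))
  full_top <- top_profiles(small, k_rows = 16)
  expect_equal(nrow(full_top), 16)
  expect_true(all(diff(full_top$positive_lr_pct) <= 0))
  expect_equal(sort(full_top$explanation_number), as.numeric(1:16))

  # agrees with sorting the brute-force enumeration
  rows <- collect_explanations(enumerate_profiles(small))
  ord <- order(-rows$positive_lr_pct, rows$explanation_number)
  expect_equal(full_top$explanation_number, rows$explanation_number[ord])
})

test_that("top-k tie-breaking stays exact across zero-weight plateaus", {
  wt <- ct_weights()  # contains two zero weights
  top <- top_profiles(wt, k_rows = 5)
  expect_true(all(diff(top$positive_lr_pct) <= 0))
  # rows 1-4: full profile plus the three ways to drop only zero weights
  expect_equal(top$positive_lr_pct[1:4], rep(percent_value(wt$total), 4))
  expect_true(all(diff(top$explanation_number[1:4]) > 0))
})

test_that("by_lr_desc order streams rows by decreasing score", {
  ds <- generate_dataset(synthetic_spec(n_variables = 7, seed = 29))
  wt <- relative_weights(ds)
  rows <- collect_explanations(enumerate_profiles(wt, order = "by_lr_desc"))
  expect_equal(nrow(rows), 128)
  expect_true(all(diff(rows$positive_lr_pct) <= 0))
  expect_equal(rows$explanation_number[1], 1)
  # same rows as binary order, just permuted
  expect_equal(sort(rows$explanation_number), as.numeric(1:128))
})

test_that("oversized enumerations refuse without force", {
  ds <- generate_dataset(synthetic_spec(n_variables = 25, count_law = "uniform",
                                        count_range = c(1, 9), seed = 1))
  wt <- relative_weights(ds)
  expect_error(enumerate_profiles(wt), class = "relw_validation_error")
  expect_s3_class(enumerate_profiles(wt, force = TRUE), "explanation_table")
})

test_that("exported explanation tables re-import losslessly", {
  ds <- generate_dataset(synthetic_spec(n_variables = 8, seed = 6))
  wt <- relative_weights(ds)
  et <- enumerate_profiles(wt, chunk_size = 50L)  # force multiple chunks
  path <- withr::local_tempfile(fileext = ".tsv")
  write_explanations(et, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  rows <- collect_explanations(et)
  expect_equal(nrow(back), 256)
  expect_equal(back$explanation_number, rows$explanation_number)
  expect_equal(back$positive_lr_pct, rows$positive_lr_pct)
  expect_equal(as.data.frame(back[variable_names(ds)]),
               as.data.frame(rows[variable_names(ds)]))
})
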