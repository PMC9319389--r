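#' Enumerate every presence profile with its scores
#'
#' Builds the exhaustive explanation table: all `2^k` presence/absence
#' profiles over the `k` weighted variables, each with its positive and
#' negative score as percents. Rows are produced lazily in fixed-size
#' chunks, so the 19-variable CT table (524,288 rows) streams in bounded
#' memory; nothing is materialized unless you ask for it.
#'
#' Row order is `"binary"` by default: counting with the last listed
#' variable as the least-significant bit, all-present first (explanation 1)
#' down to all-absent (explanation `2^k`). This is the package's own
#' convention — published tables of this kind only pin down their first and
#' last rows, so lookups should go by profile content (see
#' [lookup_profile()]), not by row index. `"by_lr_desc"` orders rows by
#' decreasing positive score (ties by binary order); it needs an `O(2^k)`
#' score index in memory and is therefore capped at `k <= 20`.
#'
#' @param weights A `weight_table` covering all variables.
#' @param mode Scoring mode, as in [score_profile()].
#' @param order `"binary"` (streaming) or `"by_lr_desc"`.
#' @param max_k Refuse datasets with more than this many variables unless
#'   `force = TRUE` (default 24, i.e. ~16.8M rows).
#' @param force Override the `max_k` guard.
#' @param chunk_size Rows per emitted chunk.
#' @return An `explanation_table` handle with fields `total_rows`, `k`,
#'   `mode`, `order`. Consume it with [explanation_chunks()],
#'   [collect_explanations()], [stream_explanations()], or
#'   [write_explanations()].
#' @examples
#' ds <- read_counting_dataset(relw_example("covid_symptom_weights.csv"))
#' et <- enumerate_profiles(load_supplied_weights(ds))
#' et$total_rows  # 2^15
#' collect_explanations(et, n = 2)
#' @export
enumerate_profiles <- function(weights,
                               mode = c("sum_present", "complement"),
                               order = c("binary", "by_lr_desc"),
                               max_k = 24L, force = FALSE,
                               chunk_size = 65536L) {
  mode <- match.arg(mode)
  order <- match.arg(order)
  stopifnot(inherits(weights, "weight_table"))
  k <- length(weights$weights)
  total <- 2^k
  if (k > max_k && !force) {
    abort_validation(sprintf(
      "Enumerating %d variables means %s rows; pass force = TRUE if you mean it.",
      k, format(total, big.mark = ",", scientific = FALSE)
    ))
  }
  if (order == "by_lr_desc" && k > 20L) {
    abort_validation(
      "`by_lr_desc` order requires a full score index; limited to k <= 20."
    )
  }
  structure(
    list(
      weights = weights,
      mode = mode,
      order = order,
      k = k,
      total_rows = total,
      chunk_size = as.integer(chunk_size)
    ),
    class = "explanation_table"
  )
}

#' @export
print.explanation_table <- function(x, ...) {
  cat(sprintf(
    "<explanation_table> %s: %d variables, %s rows (%s mode, %s order)\n",
    x$weights$dataset_name, x$k,
    format(x$total_rows, big.mark = ",", scientific = FALSE),
    x$mode, x$order
  ))
  invisible(x)
}

#' Consume an explanation table
#'
#' `explanation_chunks()` returns a stateful generator: each call yields the
#' next chunk of rows as a tibble, then `NULL` when exhausted.
#' `collect_explanations()` materializes the first `n` rows;
#' `stream_explanations()` applies a callback to every chunk without keeping
#' any; `write_explanations()` streams the whole table to a delimited file.
#'
#' Row schema: `explanation_number`, one `+`/`-` column per variable (in
#' dataset order), `positive_lr_pct`, `negative_lr_pct` (percents rendered
#' half-up at the table's display precision; the two columns complement to
#' 100 up to display rounding).
#'
#' @param et An [enumerate_profiles()] handle.
#' @return See above; `stream_explanations()` returns the number of rows
#'   visited, invisibly `write_explanations()` returns the path.
#' @examples
#' ds <- read_counting_dataset(relw_example("covid_ct_weights.csv"))
#' et <- enumerate_profiles(load_supplied_weights(ds))
#' nxt <- explanation_chunks(et)
#' head(nxt(), 3)
#' @export
explanation_chunks <- function(et) {
  stopifnot(inherits(et, "explanation_table"))
  total <- et$total_rows
  done <- 0
  index <- if (et$order == "by_lr_desc") lr_desc_index(et) else NULL
  function() {
    if (done >= total) return(NULL)
    n <- min(et$chunk_size, total - done)
    numbers <- if (is.null(index)) {
      done + seq_len(n)
    } else {
      index[done + seq_len(n)]
    }
    done <<- done + n
    explanation_rows(et, numbers)
  }
}

#' @rdname explanation_chunks
#' @param n Maximum rows to collect (default: all — guard your memory).
#' @export
collect_explanations <- function(et, n = Inf) {
  nxt <- explanation_chunks(et)
  out <- list()
  got <- 0
  while (got < n && !is.null(chunk <- nxt())) {
    if (nrow(chunk) > n - got) chunk <- chunk[seq_len(n - got), ]
    out[[length(out) + 1L]] <- chunk
    got <- got + nrow(chunk)
  }
  do.call(rbind, out)
}

#' @rdname explanation_chunks
#' @param f Callback invoked with each chunk (a tibble); its return value is
#'   discarded.
#' @export
stream_explanations <- function(et, f) {
  nxt <- explanation_chunks(et)
  visited <- 0
  while (!is.null(chunk <- nxt())) {
    f(chunk)
    visited <- visited + nrow(chunk)
  }
  visited
}

#' @rdname explanation_chunks
#' @param path Output file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @export
write_explanations <- function(et, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  delim <- if (dialect == "tsv") "\t" else ","
  first <- TRUE
  stream_explanations(et, function(chunk) {
    readr::write_delim(chunk, path, delim = delim,
                       append = !first, col_names = first)
    first <<- FALSE
  })
  invisible(path)
}

# Decode explanation numbers (1-based, all-present first) into rows.
# Number i corresponds to bit pattern m = total - i with the LAST variable as
# the least-significant bit: i = 1 -> all bits set -> all present.
explanation_rows <- function(et, numbers) {
  k <- et$k
  w <- unname(et$weights$weights)
  m <- et$total_rows - numbers
  bits <- matrix(0, nrow = length(m), ncol = k)
  for (j in seq_len(k)) {
    bits[, j] <- (m %/% 2^(k - j)) %% 2
  }
  present_sum <- drop(bits %*% w)
  plr <- if (et$mode == "sum_present") {
    present_sum
  } else {
    present_sum + (1 - et$weights$total)
  }
  p <- et$weights$display_precision
  out <- tibble::tibble(explanation_number = numbers)
  for (j in seq_len(k)) {
    out[[et$weights$variables[j]]] <- ifelse(bits[, j] == 1, "+", "-")
  }
  out$positive_lr_pct <- percent_value(plr, p)
  out$negative_lr_pct <- percent_value(1 - plr, p)
  out
}

lr_desc_index <- function(et) {
  all_rows <- seq_len(et$total_rows)
  k <- et$k
  w <- unname(et$weights$weights)
  m <- et$total_rows - all_rows
  plr <- numeric(et$total_rows)
  for (j in seq_len(k)) {
    plr <- plr + ((m %/% 2^(k - j)) %% 2) * w[j]
  }
  order(-plr, all_rows)
}

#' Look up one profile's row without enumerating
#'
#' Random access into the explanation table: computes, in `O(k)`, the row
#' (explanation number and scores) that [enumerate_profiles()] would emit
#' for the given profile in binary order.
#'
#' @param profile A [presence_profile()].
#' @param weights A `weight_table` over the same variables.
#' @param mode Scoring mode, as in [score_profile()].
#' @return A one-row tibble with the [explanation_chunks()] schema.
#' @examples
#' ds <- read_counting_dataset(relw_example("covid_ct_weights.csv"))
#' wt <- load_supplied_weights(ds)
#' lookup_profile(presence_profile(ds, "Peripheral"), wt)  # row 524,287
#' @export
lookup_profile <- function(profile, weights,
                           mode = c("sum_present", "complement")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "presence_profile"),
            inherits(weights, "weight_table"))
  if (!identical(profile$variables, weights$variables)) {
    abort_mismatch("Profile and weight table cover different variables.")
  }
  k <- length(weights$variables)
  present <- profile$present[weights$variables]
  m <- sum(2^(k - which(present)))
  et <- enumerate_profiles(weights, mode = mode, force = TRUE)
  explanation_rows(et, numbers = et$total_rows - m)
}

#' Highest-scoring profiles without full enumeration
#'
#' Returns the `k_rows` profiles with the largest positive score, ties
#' broken by binary order (ascending explanation number). For the additive
#' score this is a k-best subset problem: dropping the smallest weights
#' first. Solved by best-first search over "dropped variable" subsets with
#' the weights sorted ascending, so cost scales with `k_rows`, not `2^k`.
#' Equal-score plateaus (zero-weight variables produce many) are drained
#' level by level so the tie-break is exact.
#'
#' @param weights A `weight_table`.
#' @param mode Scoring mode; both modes rank profiles identically (the
#'   scores differ by the table's normalization defect, a constant).
#' @param k_rows Number of rows wanted (capped at `2^k`).
#' @return A tibble of `k_rows` rows in the [explanation_chunks()] schema,
#'   ordered by decreasing positive score.
#' @examples
#' ds <- read_counting_dataset(relw_example("covid_symptom_weights.csv"))
#' top_profiles(load_supplied_weights(ds), k_rows = 2)
#' @export
top_profiles <- function(weights, mode = c("sum_present", "complement"),
                         k_rows) {
  mode <- match.arg(mode)
  stopifnot(inherits(weights, "weight_table"), k_rows >= 1)
  k <- length(weights$weights)
  total <- 2^k
  k_rows <- min(k_rows, total)
  w <- unname(weights$weights)
  asc <- order(w, seq_along(w))   # positions sorted by ascending weight
  ws <- w[asc]
  pow <- 2^(k - seq_len(k))       # indexed by original variable position
  number_of <- function(dropped) 1 + sum(pow[asc[dropped]])

  frontier <- list(list(sum = 0, dropped = integer()))
  emitted <- list()
  tol <- 1e-12
  while (length(emitted) < k_rows && length(frontier) > 0) {
    sums <- vapply(frontier, `[[`, numeric(1), "sum")
    lvl <- min(sums)
    buffer <- list()
    # drain the whole equal-sum level: expanding a level state can create
    # further states at the same level (zero-weight drops)
    repeat {
      at_level <- which(sums <= lvl + tol)
      if (length(at_level) == 0) break
      states <- frontier[at_level]
      frontier <- frontier[-at_level]
      buffer <- c(buffer, states)
      grown <- list()
      for (s in states) {
        last <- if (length(s$dropped)) s$dropped[length(s$dropped)] else 0L
        if (last < k) {
          grown[[length(grown) + 1L]] <- list(
            sum = s$sum + ws[last + 1L],
            dropped = c(s$dropped, last + 1L)
          )
          if (last >= 1L) {
            grown[[length(grown) + 1L]] <- list(
              sum = s$sum - ws[last] + ws[last + 1L],
              dropped = c(s$dropped[-length(s$dropped)], last + 1L)
            )
          }
        }
      }
      frontier <- c(frontier, grown)
      sums <- vapply(frontier, `[[`, numeric(1), "sum")
    }
    nums <- vapply(buffer, function(s) number_of(s$dropped), numeric(1))
    emitted <- c(emitted, buffer[order(nums)])
  }
  emitted <- emitted[seq_len(k_rows)]
  numbers <- vapply(emitted, function(s) number_of(s$dropped), numeric(1))
  et <- enumerate_profiles(weights, mode = mode, force = TRUE)
  explanation_rows(et, numbers = numbers)
}
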