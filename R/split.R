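#' Stratified, seeded train/test split
#'
#' Shuffles samples within each source with a seeded RNG and assigns test
#' samples per source by largest-remainder rounding of
#' `(1 - train_fraction) * n_source`, constrained so the global test count
#' equals `ceiling((1 - train_fraction) * n)`. On the default 122-sample
#' panel with `train_fraction = 0.7` this yields 85 training and 37 test
#' samples (cow manure 40/17, digestate 19/9, chicken manure 11/5, pig
#' manure 15/6).
#'
#' @param dataset a [nutri_dataset()].
#' @param train_fraction proportion of samples assigned to training,
#'   strictly between 0 and 1 (default 0.7).
#' @param seed integer seed for the per-source shuffles.
#' @return An object of class `split_plan`: `train_ids`, `test_ids`, `seed`,
#'   `train_fraction` and `achieved` (per-source train/test counts).
#' @export
stratified_split <- function(dataset, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(dataset, "nutri_dataset"),
            train_fraction > 0, train_fraction < 1)
  sources <- dataset$sources
  ids <- rownames(dataset$spectra)
  n <- length(ids)
  counts <- table(sources)
  if (any(counts < 2)) {
    stop_nutrispec("cannot stratify: source(s) with fewer than 2 samples: ",
                   paste(names(counts)[counts < 2], collapse = ", "))
  }
  n_test_total <- as.integer(ceiling((1 - train_fraction) * n))

  # Largest-remainder apportionment of the global test count across sources.
  ideal <- (1 - train_fraction) * as.numeric(counts)
  base <- floor(ideal)
  rem <- ideal - base
  short <- n_test_total - sum(base)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[bump] <- base[bump] + 1
  } else if (short < 0) {
    drop <- order(rem, decreasing = FALSE)[seq_len(-short)]
    base[drop] <- base[drop] - 1
  }
  n_test <- pmin(pmax(base, 1), as.numeric(counts) - 1)
  if (sum(n_test) != n_test_total) {
    # clamping at 1/n-1 disturbed the total; re-balance on unclamped sources
    stop_nutrispec("split infeasible: per-source sizes cannot honour the global test count")
  }

  test_ids <- character(0)
  with_seed(seed, {
    for (i in seq_along(counts)) {
      s <- names(counts)[i]
      pool <- ids[sources == s]
      pool <- pool[sample.int(length(pool))]
      test_ids <- c(test_ids, pool[seq_len(n_test[i])])
    }
  })
  train_ids <- setdiff(ids, test_ids)
  achieved <- data.frame(
    source = names(counts),
    train = as.integer(counts) - as.integer(n_test),
    test = as.integer(n_test)
  )
  structure(
    list(train_ids = train_ids, test_ids = test_ids, seed = as.integer(seed),
         train_fraction = train_fraction, achieved = achieved),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test (seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$seed))
  print(x$achieved, row.names = FALSE)
  invisible(x)
}
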