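#' Rarefaction (discovery saturation) curve
#'
#' Subsamples reads without replacement at each requested depth and counts
#' the distinct units (genes, known isoforms, novel isoforms, ...) they
#' discover, averaged over replicates. The mean curve is monotone
#' non-decreasing and reaches the total distinct-unit count at full depth.
#'
#' @param assignments Tibble `read_id`, `unit` (the unit each read maps to;
#'   reads with `NA` unit count toward depth but discover nothing), or a
#'   plain vector of unit labels.
#' @param sizes Increasing subsample sizes; all must be `<=` the number of
#'   reads.
#' @param n_reps Replicates per size (default 100).
#' @param seed Optional integer seed for reproducibility.
#' @param unit Label describing the unit (stored in the result).
#' @return An object of class `iso_rarefaction`: tibble `size`, `mean_units`,
#'   `sd_units`, with attributes `n_reps`, `unit`, `total_units`, `n_reads`.
#' @export
rarefy <- function(assignments, sizes, n_reps = 100, seed = NULL, unit = "unit") {
  if (is.data.frame(assignments)) assignments <- assignments$unit
  n <- length(assignments)
  if (any(sizes > n)) abort("subsample size exceeds the number of reads")
  if (any(sizes < 0) || n_reps < 1) abort("sizes must be >= 0 and n_reps >= 1")
  if (!is.null(seed)) set.seed(seed)
  res <- purrr::map(sort(unique(as.integer(sizes))), function(k) {
    vals <- vapply(seq_len(n_reps), function(r) {
      s <- assignments[sample.int(n, k)]
      length(unique(s[!is.na(s)]))
    }, 1L)
    tibble(size = k, mean_units = mean(vals), sd_units = stats::sd(vals))
  }) %>% bind_rows()
  structure(res,
            class = c("iso_rarefaction", class(res)),
            n_reps = n_reps, unit = unit,
            total_units = length(unique(assignments[!is.na(assignments)])),
            n_reads = n)
}

#' Closed-form expected rarefaction curve
#'
#' Hypergeometric expectation of the number of distinct units discovered in
#' a without-replacement subsample of size `k`:
#' `E = sum_i (1 - choose(N - n_i, k) / choose(N, k))` over units with
#' `n_i` reads each. Useful as an analytic check of [rarefy()].
#'
#' @param assignments As in [rarefy()].
#' @param sizes Subsample sizes.
#' @return Tibble `size`, `expected_units`.
#' @export
rarefaction_expectation <- function(assignments, sizes) {
  if (is.data.frame(assignments)) assignments <- assignments$unit
  n <- length(assignments)
  counts <- table(assignments[!is.na(assignments)])
  exp_units <- vapply(as.integer(sizes), function(k) {
    sum(1 - exp(lchoose(n - counts, k) - lchoose(n, k)))
  }, 1.0)
  tibble(size = as.integer(sizes), expected_units = exp_units)
}
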