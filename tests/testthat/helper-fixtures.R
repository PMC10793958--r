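# Shared fixtures built in code at test time.

# homogeneous Poisson train (no refractoriness) as plain sorted times
poisson_times <- function(rate, duration, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- rpois(1, rate * duration)
  sort(runif(n, 0, duration))
}

# evenly spaced spike train, spikes well separated
periodic_train <- function(n, gap = 0.2, start = 0.5, id = "u1",
                           cell_class = "PYR") {
  spike_train(id, start + gap * (seq_len(n) - 1), cell_class, 1L)
}

# brute-force lag histogram oracle: O(n^2) double loop over all pairs,
# (low, high] binning
brute_cch_counts <- function(ref, tgt, bin_width, max_lag,
                             exclude_self = FALSE) {
  edges <- seq(-max_lag, max_lag, by = bin_width)
  counts <- numeric(length(edges) - 1)
  for (i in seq_along(ref)) {
    for (j in seq_along(tgt)) {
      if (exclude_self && i == j) next
      lag <- tgt[j] - ref[i]
      if (lag > -max_lag && lag <= max_lag) {
        k <- findInterval(lag, edges, left.open = TRUE)
        counts[k] <- counts[k] + 1
      }
    }
  }
  counts
}

# brute-force hollowed median oracle
brute_hollowed_median <- function(x, h) {
  n <- length(x)
  sapply(seq_len(n), function(i) {
    idx <- setdiff(max(1, i - h):min(n, i + h), i)
    median(x[idx])
  })
}

# three-epoch set with given durations
make_epochs <- function(before = 300, experience = 60, after = 300) {
  epoch_set(c("Before", "Experience", "After"),
            cumsum(c(0, before, experience)),
            cumsum(c(before, experience, after)))
}

# slice a feature matrix from simulate_assembly_features to |lag| <= w_ms
slice_lags <- function(X, w_ms = 10) {
  lag <- as.numeric(sub("lag_", "", colnames(X)))
  X[, abs(lag) <= w_ms, drop = FALSE]
}
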