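## Spike transmission gain (STG), STG change, the row-label permutation test
## and pair-eligibility screening.

.before_after_intervals <- function(epochs) {
  rbind(epoch_bounds(epochs, "Before"), epoch_bounds(epochs, "After"))
}

#' Detect an excitatory monosynaptic connection
#'
#' Builds the count CCH (0.5-ms bins) from the combined Before and After
#' epochs, takes the hollowed-median baseline as the chance predictor, and
#' applies the Poisson excess test to the summed counts in the causal
#' monosynaptic ROI (0 < tau <= 5 ms).
#'
#' @param pre,post Presynaptic and postsynaptic `spike_train`s.
#' @param epochs An `epoch_set` with Before and After epochs.
#' @param bin_width_s,max_lag_s,half_width_s,roi_s CCH and baseline
#'   parameters (defaults 0.5 ms, 30 ms, 10 ms, 5 ms). The transmission
#'   module uses a 10-ms baseline half-width so that the monosynaptic peak
#'   occupies only a small fraction of the median window.
#' @return p-value of the connection (small = connected).
#' @export
detect_monosynaptic <- function(pre, post, epochs, bin_width_s = 0.0005,
                                max_lag_s = 0.030, half_width_s = 0.010,
                                roi_s = 0.005) {
  ints <- .before_after_intervals(epochs)
  pre_r <- restrict(pre, ints)
  post_r <- restrict(post, ints)
  if (!n_spikes(pre_r) || !n_spikes(post_r)) {
    stop("both trains need at least one spike in the combined Before/After epochs")
  }
  cch <- compute_cch(pre_r, post_r, bin_width_s, max_lag_s)
  base <- hollowed_median_baseline(cch, half_width_s)
  roi <- .roi_bins(cch, roi_s)
  poisson_excess_test(sum(cch$counts[roi]), sum(base[roi]))
}

#' Spike transmission gain of a pair within an epoch
#'
#' The STG is the area under the causal peak of the deconvolved,
#' baseline-subtracted transmission curve: the peak bin is located within the
#' monosynaptic ROI (0 < tau <= 5 ms) and the integration region is extended
#' left (bounded by zero lag) and right until the curve first crosses zero.
#' Units are expected excess postsynaptic spikes per presynaptic spike. When
#' no bin in the ROI is positive the STG is 0.
#'
#' @param pre,post Presynaptic and postsynaptic `spike_train`s.
#' @param interval `c(start, end)` epoch bounds (or any interval set).
#' @param bin_width_s,max_lag_s,half_width_s,roi_s,reg Estimation parameters.
#' @param details Logical; attach the transmission curve as an attribute.
#' @return Numeric STG (dimensionless, >= 0).
#' @export
compute_stg <- function(pre, post, interval, bin_width_s = 0.0005,
                        max_lag_s = 0.030, half_width_s = 0.010,
                        roi_s = 0.005, reg = 1e-6, details = FALSE) {
  pre_r <- restrict(pre, interval)
  post_r <- restrict(post, interval)
  if (!n_spikes(pre_r)) stop("no presynaptic spikes in the interval")
  cch <- compute_cch(pre_r, post_r, bin_width_s, max_lag_s)
  ach <- compute_cch(pre_r, pre_r, bin_width_s, max_lag_s, exclude_self = TRUE)
  curve <- deconvolve_transmission(cch, ach, half_width_s, reg)
  zb <- .zero_bin(cch)
  n_roi <- as.integer(round(roi_s / bin_width_s))
  stg <- cpp_stg_region(curve$excess_per_spike, zb, n_roi)
  if (details) attr(stg, "curve") <- curve
  stg
}

#' STG change between two epochs
#'
#' Base-2 logarithm of the ratio of the After-epoch STG to the Before-epoch
#' STG: +1 means the transmission gain doubled, -1 that it halved, 0 no
#' change. Undefined (`NA`) when either STG is non-positive; such pairs are
#' excluded from change analyses.
#'
#' @param stg_before,stg_after STG estimates (vectorized).
#' @return log2 ratio(s); `NA` where undefined.
#' @export
stg_change <- function(stg_before, stg_after) {
  out <- suppressWarnings(log2(stg_after / stg_before))
  out[!(is.finite(stg_before) & is.finite(stg_after) &
          stg_before > 0 & stg_after > 0)] <- NA_real_
  out
}

#' Permutation test for the consistency of an STG change
#'
#' Builds a binary spike-time lag matrix (0.5-ms bins over -30 < tau <= 30
#' ms): one row per presynaptic spike from the Before and After epochs, one
#' column per lag bin, entries marking postsynaptic spike occupancy. The
#' observed STG change is computed from the count CCHs obtained by summing
#' rows according to the true epoch labels; the null distribution comes from
#' random permutations of the row labels, each recomputing both STGs through
#' the identical deconvolution path. The presynaptic ACH kernel is fixed to
#' the label-invariant combined train. Two-tailed p-value with the +1
#' correction: `(1 + #{|shuffled| >= |observed|}) / (n_valid + 1)`, so the
#' minimal attainable p is `1 / (n_shuffles + 1)`. Shuffles with a
#' non-positive STG in either partition are discarded and redrawn (capped at
#' `3 * n_shuffles` attempts).
#'
#' @param pre,post Presynaptic and postsynaptic `spike_train`s.
#' @param epochs `epoch_set` with Before and After epochs.
#' @param n_shuffles Number of label permutations (default 2000).
#' @param seed Optional integer seed.
#' @param bin_width_s,max_lag_s,half_width_s,roi_s,reg Estimation parameters.
#' @param alpha Two-tailed significance threshold for calling a direction
#'   (default 0.05, i.e. 2.5 percent per direction).
#' @return List with `observed_change`, `p_change`, `direction`
#'   (`"increase"`, `"decrease"` or `"none"`), `null_changes`, `n_valid`,
#'   `n_attempts`.
#' @export
permutation_test_stg_change <- function(pre, post, epochs, n_shuffles = 2000,
                                        seed = NULL, bin_width_s = 0.0005,
                                        max_lag_s = 0.030,
                                        half_width_s = 0.010, roi_s = 0.005,
                                        reg = 1e-6, alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  b_int <- epoch_bounds(epochs, "Before")
  a_int <- epoch_bounds(epochs, "After")
  pre_b <- restrict(.spike_times(pre), matrix(b_int, 1))
  pre_a <- restrict(.spike_times(pre), matrix(a_int, 1))
  if (length(pre_b) < 2L || length(pre_a) < 2L) {
    stop("need at least 2 presynaptic spikes in each of the Before and After epochs")
  }
  ints <- rbind(b_int, a_int)
  post_c <- restrict(.spike_times(post), ints)
  pre_c <- c(pre_b, pre_a)

  grid <- .make_grid(bin_width_s, max_lag_s, "edge")
  M <- cpp_lag_matrix(pre_c, post_c, grid$lo, grid$bin_width_s, grid$n_bins)
  labels <- c(rep(TRUE, length(pre_b)), rep(FALSE, length(pre_a)))

  ach <- compute_cch(pre_c, pre_c, bin_width_s, max_lag_s, exclude_self = TRUE)
  kern <- .ach_kernel(ach, half_width_s)
  P <- .decon_operator(kern$kernel_norm, kern$d_offsets, grid$n_bins, reg)
  h <- as.integer(round(half_width_s / bin_width_s))
  n_roi <- as.integer(round(roi_s / bin_width_s))

  res <- cpp_perm_stg_change(M, labels, P, h, kern$zb, n_roi,
                             as.integer(n_shuffles), 3L * as.integer(n_shuffles))
  obs <- res$observed
  nullv <- res$null
  if (!is.finite(obs) || !length(nullv)) {
    return(list(observed_change = obs, p_change = NA_real_,
                direction = "none", null_changes = nullv,
                n_valid = length(nullv), n_attempts = res$attempts))
  }
  p <- (1 + sum(abs(nullv) >= abs(obs))) / (length(nullv) + 1)
  direction <- if (p < alpha) {
    if (obs > 0) "increase" else "decrease"
  } else "none"
  list(observed_change = obs, p_change = p, direction = direction,
       null_changes = nullv, n_valid = length(nullv),
       n_attempts = res$attempts)
}

#' Screen one presynaptic-postsynaptic pair
#'
#' Computes the quantities pair selection and plasticity analyses need: the
#' combined-epoch connection p-value, per-epoch window counts, the location
#' of the CCH maximum, and the Before/After STGs with their change.
#'
#' @param pre,post `spike_train`s.
#' @param epochs `epoch_set` with Before and After epochs.
#' @param bin_width_s,max_lag_s,half_width_s,roi_s,reg Estimation parameters.
#' @return One-row data frame with columns `pre_id`, `post_id`,
#'   `counts_before`, `counts_after`, `peak_in_roi`, `p_connect`,
#'   `stg_before`, `stg_after`, `stg_change`.
#' @export
evaluate_pair <- function(pre, post, epochs, bin_width_s = 0.0005,
                          max_lag_s = 0.030, half_width_s = 0.010,
                          roi_s = 0.005, reg = 1e-6) {
  b_int <- epoch_bounds(epochs, "Before")
  a_int <- epoch_bounds(epochs, "After")
  cch_b <- compute_cch(restrict(pre, b_int), restrict(post, b_int),
                       bin_width_s, max_lag_s)
  cch_a <- compute_cch(restrict(pre, a_int), restrict(post, a_int),
                       bin_width_s, max_lag_s)
  roi <- .roi_bins(cch_b, roi_s)
  peak_in_roi <- which.max(cch_b$counts) %in% roi ||
    which.max(cch_a$counts) %in% roi
  p_connect <- detect_monosynaptic(pre, post, epochs, bin_width_s, max_lag_s,
                                   half_width_s, roi_s)
  sb <- compute_stg(pre, post, b_int, bin_width_s, max_lag_s, half_width_s,
                    roi_s, reg)
  sa <- compute_stg(pre, post, a_int, bin_width_s, max_lag_s, half_width_s,
                    roi_s, reg)
  data.frame(pre_id = .unit_id(pre, "pre"), post_id = .unit_id(post, "post"),
             counts_before = sum(cch_b$counts), counts_after = sum(cch_a$counts),
             peak_in_roi = peak_in_roi, p_connect = p_connect,
             stg_before = sb, stg_after = sa,
             stg_change = stg_change(sb, sa),
             stringsAsFactors = FALSE)
}

#' Flag pairs eligible for plasticity analysis
#'
#' A pair is eligible when (i) an excitatory monosynaptic connection is
#' detected in the combined Before+After CCH (`p_connect < alpha`), (ii) at
#' least `min_counts` CCH counts accumulated in -30 < tau <= 30 ms in each of
#' the Before and After epochs, and (iii) the global maximum of the Before or
#' the After CCH lies in the causal monosynaptic ROI (0 < tau <= 5 ms).
#'
#' @param pairs Data frame as returned by [evaluate_pair()] (row-bound).
#' @param alpha Connection significance threshold (default 0.001).
#' @param min_counts Minimum per-epoch window counts (default 400).
#' @return `pairs` with a logical `eligible` column added.
#' @export
select_eligible_pairs <- function(pairs, alpha = 0.001, min_counts = 400) {
  needed <- c("p_connect", "counts_before", "counts_after", "peak_in_roi")
  missing <- setdiff(needed, names(pairs))
  if (length(missing)) stop("pairs is missing column(s): ",
                            paste(missing, collapse = ", "))
  pairs$eligible <- pairs$p_connect < alpha &
    pairs$counts_before >= min_counts &
    pairs$counts_after >= min_counts &
    pairs$peak_in_roi
  pairs
}
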