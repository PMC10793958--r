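## Correlograms: CCH / ACH / PSTH, hollowed-median baselines, deconvolved
## transmission curves, and the Poisson excess-count test.

.make_grid <- function(bin_width_s, max_lag_s, align) {
  w <- bin_width_s
  if (w <= 0) stop("bin_width_s must be positive")
  k <- max_lag_s / w
  if (abs(k - round(k)) > 1e-6) {
    stop("max_lag_s must be a multiple of bin_width_s")
  }
  k <- round(k)
  if (align == "edge") {
    # bins (low, high] with edges on multiples of the bin width; even count,
    # zero is a bin edge: matches ROIs written as 0 < tau <= 5 ms
    nb <- 2L * k
    lo <- -max_lag_s
  } else {
    # bins centered on multiples of the bin width; odd count, the middle bin
    # straddles zero lag
    nb <- 2L * k + 1L
    lo <- -max_lag_s - w / 2
  }
  centers <- lo + (seq_len(nb) - 0.5) * w
  list(lo = lo, n_bins = nb, centers = centers, bin_width_s = w)
}

# 1-based index of the bin whose right-closed interval contains lag 0
.zero_bin <- function(corr) {
  as.integer(ceiling((0 - corr$lo) / corr$bin_width_s - 1e-9))
}

# 1-based indices of the causal ROI 0 < tau <= roi_s (edge grids); for
# centered grids, bins with centers in (0, roi_s]
.roi_bins <- function(corr, roi_s) {
  zb <- .zero_bin(corr)
  n <- round(roi_s / corr$bin_width_s)
  seq.int(zb + 1L, zb + n)
}

.new_correlogram <- function(ref_id, tgt_id, grid, counts, n_ref, n_tgt,
                             scale, align, kind) {
  structure(
    list(ref_id = ref_id, tgt_id = tgt_id, bin_width_s = grid$bin_width_s,
         lo = grid$lo, n_bins = grid$n_bins, lags = grid$centers,
         counts = as.numeric(counts), n_ref = n_ref, n_tgt = n_tgt,
         rate = as.numeric(counts) / (n_ref * grid$bin_width_s),
         scale = scale, align = align, kind = kind),
    class = "correlogram"
  )
}

#' Cross- or auto-correlation histogram of two spike trains
#'
#' Counts spike-time lags `tgt - ref` in bins that are half-open on the left
#' and closed on the right, `(low, high]`. With `align = "edge"` the bin
#' edges lie on multiples of the bin width and zero lag is an edge (the
#' convention behind ROIs such as 0 < tau <= 5 ms); with `align = "center"`
#' bins are centered on multiples of the bin width and the middle bin
#' straddles zero. When both inputs are `spike_train`s with the same unit id
#' the result is an autocorrelation histogram and self-pairs are excluded.
#'
#' @param ref,tgt Reference and target trains (`spike_train` or numeric
#'   vectors of sorted times in seconds).
#' @param bin_width_s Bin width in seconds (default 0.5 ms).
#' @param max_lag_s Maximum lag in seconds; must be a multiple of the bin
#'   width (default 30 ms).
#' @param scale `"count"` or `"rate"`; the returned object always carries
#'   both the raw counts and the conditional rate
#'   `counts / (n_ref * bin_width_s)` in spikes/s.
#' @param align Bin-grid alignment, `"edge"` (default) or `"center"`.
#' @param exclude_self Logical; drop same-index pairs (defaults to `TRUE`
#'   exactly when `ref` and `tgt` are trains of the same unit).
#' @return An object of class `correlogram`.
#' @export
compute_cch <- function(ref, tgt, bin_width_s = 0.0005, max_lag_s = 0.030,
                        scale = c("count", "rate"), align = c("edge", "center"),
                        exclude_self = NULL) {
  scale <- match.arg(scale)
  align <- match.arg(align)
  rt <- .spike_times(ref)
  tt <- .spike_times(tgt)
  if (!length(rt)) stop("empty reference train: conditional rate undefined")
  if (is.null(exclude_self)) {
    exclude_self <- inherits(ref, "spike_train") &&
      inherits(tgt, "spike_train") && identical(ref$unit_id, tgt$unit_id)
  }
  grid <- .make_grid(bin_width_s, max_lag_s, align)
  counts <- cpp_count_lags(rt, tt, grid$lo, grid$bin_width_s, grid$n_bins,
                           exclude_self)
  .new_correlogram(.unit_id(ref, "ref"), .unit_id(tgt, "tgt"), grid, counts,
                   length(rt), length(tt), scale, align,
                   kind = if (exclude_self) "ach" else "cch")
}

#' Peristimulus time histogram
#'
#' Bins spike times relative to stimulus onsets (positive lag = spike after
#' onset) and scales to a conditional rate per event.
#'
#' @param train A `spike_train` or numeric spike-time vector.
#' @param events A `stim_events` object or numeric onset vector.
#' @param bin_width_s Bin width (default 1 ms).
#' @param window_s Half-width of the lag window (default 50 ms).
#' @param align Bin alignment as in [compute_cch()].
#' @return A `correlogram` with `ref_id = "events"`.
#' @export
psth <- function(train, events, bin_width_s = 0.001, window_s = 0.050,
                 align = c("edge", "center")) {
  align <- match.arg(align)
  onsets <- if (inherits(events, "stim_events")) events$onsets else
    as.numeric(events)
  if (!length(onsets)) stop("no events: PSTH undefined")
  tt <- .spike_times(train)
  grid <- .make_grid(bin_width_s, window_s, align)
  counts <- cpp_count_lags(onsets, tt, grid$lo, grid$bin_width_s, grid$n_bins,
                           FALSE)
  .new_correlogram("events", .unit_id(train, "unit"), grid, counts,
                   length(onsets), length(tt), "rate", align, kind = "psth")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram:%s> %s -> %s, %d bins of %.2f ms, %d ref / %d tgt spikes\n",
              x$kind, x$ref_id, x$tgt_id, x$n_bins, 1000 * x$bin_width_s,
              x$n_ref, x$n_tgt))
  invisible(x)
}

#' @export
as.data.frame.correlogram <- function(x, ...) {
  data.frame(lag_center_s = x$lags, count = x$counts, rate_spk_s = x$rate)
}

#' Hollowed-median baseline of a correlogram
#'
#' Running median over bins within `half_width_s` of each bin, excluding the
#' bin itself ("hollowed"); the window truncates at the edges. This slow-
#' timescale predictor serves as the chance-level baseline for transmission
#' peaks, closed-loop efficiency and synchrony.
#'
#' @param x A `correlogram`, or a numeric count vector.
#' @param half_width_s Half-width of the median window in seconds (default
#'   5 ms); must be a multiple of the bin width.
#' @param bin_width_s Bin width; only needed when `x` is a bare numeric
#'   vector.
#' @return Numeric per-bin baseline (same units as the input counts).
#' @export
hollowed_median_baseline <- function(x, half_width_s = 0.005,
                                     bin_width_s = NULL) {
  if (inherits(x, "correlogram")) {
    counts <- x$counts
    bin_width_s <- x$bin_width_s
  } else {
    counts <- as.numeric(x)
    if (is.null(bin_width_s)) stop("bin_width_s required for numeric input")
  }
  h <- half_width_s / bin_width_s
  if (abs(h - round(h)) > 1e-6) {
    stop("half_width_s must be a multiple of the bin width")
  }
  h <- as.integer(round(h))
  if (2L * h + 1L < 3L) stop("median window smaller than 3 bins")
  cpp_hollowed_median(counts, h)
}

## ------------------------------------------------------------------
## deconvolution

# Solve operator for the deconvolution system. kernel_norm is the presyn
# autocorrelation excess per reference spike with 1 at zero offset, indexed
# by discrete bin offsets d = (1:nb) - zb. Returns P with
# curve = P %*% (excess counts / n_ref).
.decon_operator <- function(kernel_norm, d_offsets, nb, reg = 1e-6) {
  kv <- numeric(2L * nb - 1L)              # offsets -(nb-1) .. (nb-1)
  kv[d_offsets + nb] <- kernel_norm
  K <- matrix(kv[outer(seq_len(nb), seq_len(nb), `-`) + nb], nb, nb)
  lambda <- reg * sum(K * K) / nb
  solve(crossprod(K) + diag(lambda, nb), t(K))
}

.ach_kernel <- function(ach, half_width_s) {
  base <- hollowed_median_baseline(ach, half_width_s)
  ex <- ach$counts - base
  zb <- .zero_bin(ach)
  ex[zb] <- ach$n_ref            # identity mass: every spike at zero lag
  list(kernel_norm = ex / ach$n_ref, d_offsets = seq_len(ach$n_bins) - zb,
       zb = zb)
}

#' Deconvolved spike-transmission curve
#'
#' Estimates the causal transmission curve of a presynaptic-postsynaptic pair
#' by removing the slow CCH baseline (hollowed median) and deconvolving the
#' presynaptic autocorrelation structure. The excess CCH is modeled as the
#' convolution of the presynaptic ACH kernel (ACH excess over its own
#' hollowed-median baseline, with the zero-lag bin set to the number of
#' reference spikes) with the transmission curve; the finite-window Toeplitz
#' system is solved by least squares with a small Tikhonov ridge
#' (`lambda = reg * tr(K'K) / n_bins`). For a Poisson reference train (flat
#' ACH) the curve reduces to `(counts - baseline) / (n_ref * bin_width)`.
#'
#' @param cch Count CCH of the pair (reference = presynaptic unit).
#' @param ach Count ACH of the reference train over the same epoch, on the
#'   same bin grid.
#' @param half_width_s Hollowed-median half-width (default 5 ms).
#' @param reg Tikhonov regularization scale (default 1e-6).
#' @return An object of class `transmission_curve` with elements `lags`,
#'   `rate` (excess conditional rate, spk/s), `excess_per_spike` (excess
#'   postsynaptic spikes per presynaptic spike per bin) and `baseline`.
#' @export
deconvolve_transmission <- function(cch, ach, half_width_s = 0.005,
                                    reg = 1e-6) {
  if (!inherits(cch, "correlogram") || !inherits(ach, "correlogram")) {
    stop("cch and ach must be correlograms")
  }
  if (ach$n_bins != cch$n_bins || abs(ach$bin_width_s - cch$bin_width_s) > 1e-12 ||
      abs(ach$lo - cch$lo) > 1e-12) {
    stop("cch and ach must share the same bin grid")
  }
  if (ach$n_ref != cch$n_ref) {
    stop("ach must be computed from the reference train of the cch over the same epoch")
  }
  base <- hollowed_median_baseline(cch, half_width_s)
  kern <- .ach_kernel(ach, half_width_s)
  P <- .decon_operator(kern$kernel_norm, kern$d_offsets, cch$n_bins, reg)
  b <- (cch$counts - base) / cch$n_ref
  cvec <- drop(P %*% b)
  structure(
    list(lags = cch$lags, rate = cvec / cch$bin_width_s,
         excess_per_spike = cvec, baseline = base,
         bin_width_s = cch$bin_width_s, lo = cch$lo, n_bins = cch$n_bins,
         n_ref = cch$n_ref),
    class = "transmission_curve"
  )
}

#' @export
print.transmission_curve <- function(x, ...) {
  cat(sprintf("<transmission_curve> %d bins of %.2f ms, peak %.3f spk/s\n",
              x$n_bins, 1000 * x$bin_width_s, max(x$rate)))
  invisible(x)
}

#' Poisson excess-count test
#'
#' Upper-tail Poisson probability of observing `n_obs` or more counts when
#' `n_expected` are expected, with a continuity correction:
#' `p = 1 - F(n_obs - 1; lambda) - 0.5 * f(n_obs; lambda)` where `F`/`f` are
#' the Poisson CDF/PMF at `lambda = n_expected`. The result is clipped to
#' (0, 1).
#'
#' @param n_obs Observed count(s), non-negative integers.
#' @param n_expected Expected count(s) under the chance baseline.
#' @return p-value(s) in (0, 1).
#' @export
poisson_excess_test <- function(n_obs, n_expected) {
  if (any(n_obs < 0)) stop("n_obs must be non-negative")
  if (any(n_expected < 0)) stop("n_expected must be non-negative")
  n_obs <- round(n_obs)
  p <- 1 - ppois(n_obs - 1, n_expected) - 0.5 * dpois(n_obs, n_expected)
  if (any(n_expected == 0 & n_obs > 0)) {
    warning("zero expected counts with positive observations: p clipped to the minimum")
  }
  pmin(pmax(p, 1e-300), 1 - 1e-16)
}
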