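## Zero-lag synchrony effect size between spike trains and its change across
## epochs.

#' Zero-lag synchrony effect size of a pair of spike trains
#'
#' Counts coincident spikes in the synchrony ROI (lags in (-roi_s, roi_s]
#' of the 0.5-ms-bin CCH), normalizes by the geometric mean of the two spike
#' counts to obtain `eta_sync = n_sync / sqrt(N1 * N2)` (bounded [0, 1],
#' approaching 1 when every spike of one train is synchronous with the
#' other), and derives the chance level `eta_pred` from the hollowed-median
#' predictor of the CCH by timescale separation. The synchrony measure is
#' `delta_eta = eta_sync - eta_pred` (bounded [-1, 1]); significance comes
#' from the Poisson excess test of `n_sync` against `n_pred`.
#'
#' @param train_1,train_2 `spike_train`s (distinct units).
#' @param bin_width_s CCH bin width (default 0.5 ms).
#' @param roi_s Synchrony ROI half-width (default 1 ms).
#' @param half_width_s Hollowed-median half-width (default 5 ms).
#' @param max_lag_s CCH window half-width (default 30 ms).
#' @param intervals Optional interval set restricting both trains (e.g. one
#'   epoch, or the session minus stimulation times).
#' @return An object of class `sync_result` with fields `id_1`, `id_2`,
#'   `n_sync`, `n_pred`, `eta_sync`, `eta_pred`, `delta_eta`, `p_sync`,
#'   `N1`, `N2`.
#' @export
sync_measure <- function(train_1, train_2, bin_width_s = 0.0005,
                         roi_s = 0.001, half_width_s = 0.005,
                         max_lag_s = 0.030, intervals = NULL) {
  if (!is.null(intervals)) {
    train_1 <- restrict(train_1, intervals)
    train_2 <- restrict(train_2, intervals)
  }
  N1 <- n_spikes(train_1)
  N2 <- n_spikes(train_2)
  if (!N1 || !N2) stop("both trains need at least one spike")
  cch <- compute_cch(train_1, train_2, bin_width_s, max_lag_s,
                     exclude_self = FALSE)
  base <- hollowed_median_baseline(cch, half_width_s)
  zb <- .zero_bin(cch)
  k <- as.integer(round(roi_s / bin_width_s))
  roi <- seq.int(zb - k + 1L, zb + k)     # (-roi_s, roi_s]
  n_sync <- sum(cch$counts[roi])
  n_pred <- sum(base[roi])
  gm <- sqrt(as.numeric(N1) * N2)
  structure(
    list(id_1 = .unit_id(train_1, "unit1"), id_2 = .unit_id(train_2, "unit2"),
         n_sync = n_sync, n_pred = n_pred,
         eta_sync = n_sync / gm, eta_pred = n_pred / gm,
         delta_eta = (n_sync - n_pred) / gm,
         p_sync = as.numeric(poisson_excess_test(n_sync, n_pred)),
         N1 = N1, N2 = N2),
    class = "sync_result"
  )
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> %s ~ %s: eta_sync %.4f, delta_eta %.4f (p = %.3g)\n",
              x$id_1, x$id_2, x$eta_sync, x$delta_eta, x$p_sync))
  invisible(x)
}

#' Synchrony change between two epochs
#'
#' Base-2 logarithm of the ratio of the After-epoch to the Before-epoch
#' synchrony measure (`delta_eta`). Undefined (`NA`) when either measure is
#' non-positive.
#'
#' @param sync_before,sync_after `sync_result` objects or bare `delta_eta`
#'   values.
#' @return log2 ratio; `NA` where undefined.
#' @export
sync_change <- function(sync_before, sync_after) {
  d_b <- if (inherits(sync_before, "sync_result")) sync_before$delta_eta else
    as.numeric(sync_before)
  d_a <- if (inherits(sync_after, "sync_result")) sync_after$delta_eta else
    as.numeric(sync_after)
  out <- suppressWarnings(log2(d_a / d_b))
  out[!(is.finite(d_b) & is.finite(d_a) & d_b > 0 & d_a > 0)] <- NA_real_
  out
}
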