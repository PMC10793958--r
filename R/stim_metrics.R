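## Closed-loop feedback quantification: closed-loop efficiency (CLE) of
## presynaptic units and light activation of postsynaptic units.

#' Closed-loop efficiency of a unit
#'
#' Estimates what fraction of a unit's spikes triggered light stimuli. A PSTH
#' (1-ms bins) is built around stimulus onsets; the chance baseline is the
#' hollowed-median filter of the PSTH; the excess counts in the pre-onset ROI
#' (-5 ms, 0] are summed and divided by the unit's total spike count in the
#' analyzed period, then clipped to [0, 1]. A CLE of 1 means every spike was
#' followed by exactly one stimulus; 0 means none were. The trigger p-value
#' is the Poisson excess test of the ROI counts against the baseline
#' expectation.
#'
#' @param train `spike_train` of the candidate trigger unit.
#' @param events `stim_events` (at least one event).
#' @param bin_width_s PSTH bin width (default 1 ms).
#' @param window_s PSTH half-window (default 50 ms).
#' @param half_width_s Hollowed-median half-width (default 5 ms).
#' @param roi_s Width of the pre-onset ROI (default 5 ms).
#' @param analysis_interval `c(start, end)` period whose spikes form the CLE
#'   denominator; defaults to the event range padded by the PSTH window.
#'   Pass the Experience epoch bounds for session analyses.
#' @param alpha Significance threshold for the trigger flag (default 0.001).
#' @return List with `cle`, `p_trigger`, `is_trigger`, `n_spikes`,
#'   `n_events`.
#' @export
closed_loop_efficiency <- function(train, events, bin_width_s = 0.001,
                                   window_s = 0.050, half_width_s = 0.005,
                                   roi_s = 0.005, analysis_interval = NULL,
                                   alpha = 0.001) {
  onsets <- if (inherits(events, "stim_events")) events$onsets else
    as.numeric(events)
  if (!length(onsets)) stop("no events: CLE undefined")
  tt <- .spike_times(train)
  if (!length(tt)) stop("no spikes: CLE undefined")
  if (is.null(analysis_interval)) {
    analysis_interval <- c(min(onsets) - window_s, max(onsets) + window_s)
  }
  n_sp <- sum(.in_intervals(tt, matrix(analysis_interval, 1)))
  if (!n_sp) {
    return(list(cle = 0, p_trigger = 1, is_trigger = FALSE, n_spikes = 0L,
                n_events = length(onsets)))
  }
  ps <- psth(train, onsets, bin_width_s, window_s)
  base <- hollowed_median_baseline(ps, half_width_s)
  zb <- .zero_bin(ps)
  n_roi <- as.integer(round(roi_s / bin_width_s))
  roi <- seq.int(zb - n_roi + 1L, zb)      # (-roi_s, 0]
  excess <- sum(ps$counts[roi] - base[roi])
  cle <- min(max(excess / n_sp, 0), 1)
  p_trigger <- poisson_excess_test(sum(ps$counts[roi]), sum(base[roi]))
  list(cle = cle, p_trigger = as.numeric(p_trigger),
       is_trigger = p_trigger < alpha, n_spikes = n_sp,
       n_events = length(onsets))
}

#' Light response of a postsynaptic unit
#'
#' Compares the unit's PSTH rate during the light-response window
#' [10, 30) ms after stimulus onset with the pre-onset baseline rate
#' measured over the 15-ms period from 30 ms to 15 ms before onset.
#' `light_gain` is the ratio of the two rates; the activation p-value is the
#' Poisson excess test of the response-window counts against the baseline
#' expectation scaled to the window length.
#'
#' @param train Postsynaptic `spike_train`.
#' @param events `stim_events` (at least one event).
#' @param bin_width_s PSTH bin width (default 1 ms).
#' @param window_s PSTH half-window (default 50 ms).
#' @param alpha Significance threshold for the light-activated flag
#'   (default 0.05).
#' @return List with `light_gain`, `p_light`, `is_light_activated`,
#'   `response_rate`, `baseline_rate`. `light_gain` is `NA` (flagged) when
#'   the baseline window holds no spikes.
#' @export
light_response <- function(train, events, bin_width_s = 0.001,
                           window_s = 0.050, alpha = 0.05) {
  onsets <- if (inherits(events, "stim_events")) events$onsets else
    as.numeric(events)
  if (!length(onsets)) stop("no events: light response undefined")
  ps <- psth(train, onsets, bin_width_s, window_s)
  zb <- .zero_bin(ps)
  per_bin <- function(ms) as.integer(round(ms / 1000 / bin_width_s))
  resp <- seq.int(zb + per_bin(10) + 1L, zb + per_bin(30))   # (10, 30] ms
  basew <- seq.int(zb - per_bin(30) + 1L, zb - per_bin(15))  # (-30, -15] ms
  resp_counts <- sum(ps$counts[resp])
  base_counts <- sum(ps$counts[basew])
  resp_rate <- resp_counts / (length(onsets) * length(resp) * bin_width_s)
  base_rate <- base_counts / (length(onsets) * length(basew) * bin_width_s)
  if (base_counts == 0) {
    return(list(light_gain = NA_real_, p_light = NA_real_,
                is_light_activated = NA, response_rate = resp_rate,
                baseline_rate = base_rate))
  }
  expected <- base_counts * length(resp) / length(basew)
  p_light <- as.numeric(poisson_excess_test(resp_counts, expected))
  list(light_gain = resp_rate / base_rate, p_light = p_light,
       is_light_activated = p_light < alpha, response_rate = resp_rate,
       baseline_rate = base_rate)
}
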