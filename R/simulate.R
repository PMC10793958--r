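## Synthetic closed-loop sessions with known ground truth: refractory-Poisson
## presynaptic (PYR) trains, converging assemblies onto postsynaptic (PV)
## units, closed-loop stimulation with imperfect detection, light-induced
## rate gain, and injected multiplicative plasticity of the transmission
## probability.

#' Simulation configuration
#'
#' Returns a validated configuration list for [generate_session()]. Defaults
#' follow the closed-loop experimental design the simulator emulates:
#' 45/55/45-min Before/Experience/After epochs, a 3-ms detection delay, 30-ms
#' light stimuli, a 20-ms dead time, presynaptic rates of 0.5-5 spk/s,
#' postsynaptic rates of 5-30 spk/s, transmission probabilities of
#' 0.005-0.2 drawn log-uniformly per pair, and a light-induced postsynaptic
#' rate gain of 1.56.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_assemblies = 3L,
    presyn_per_assembly = 4L,
    presyn_rate_range = c(0.5, 5),
    postsyn_rate_range = c(5, 30),
    refractory_s = 0.002,
    transmission_prob_range = c(0.005, 0.2),
    kernel_lo_s = 0.0005,          # rectangular excess-rate kernel support
    kernel_hi_s = 0.0035,
    plasticity_factors = 1,        # recycled per assembly
    plasticity_mode = "assembly",  # "assembly" (shared) or "pair" (independent)
    pair_factor_range = c(0.4, 2.5),
    epoch_durations_s = c(Before = 2700, Experience = 3300, After = 2700),
    triggers_per_assembly = 1L,
    detection_prob = 0.5,
    delay_s = 0.003,
    stim_duration_s = 0.030,
    dead_time_s = 0.020,
    light_gain = 1.56
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  # YAML configs deliver vectors as lists; flatten the numeric fields
  for (nm in c("presyn_rate_range", "postsyn_rate_range",
               "transmission_prob_range", "plasticity_factors",
               "pair_factor_range", "epoch_durations_s")) {
    cfg[[nm]] <- unlist(cfg[[nm]])
  }
  stopifnot(cfg$n_assemblies >= 1, cfg$presyn_per_assembly >= 1,
            all(cfg$presyn_rate_range > 0), all(cfg$postsyn_rate_range > 0),
            cfg$refractory_s >= 0, cfg$light_gain > 0,
            all(cfg$plasticity_factors > 0),
            all(cfg$transmission_prob_range >= 0),
            all(cfg$transmission_prob_range < 1),
            cfg$kernel_hi_s > cfg$kernel_lo_s, cfg$kernel_lo_s >= 0,
            cfg$detection_prob >= 0, cfg$detection_prob <= 1,
            all(cfg$epoch_durations_s > 0),
            cfg$plasticity_mode %in% c("assembly", "pair"))
  structure(cfg, class = c("sim_config", "list"))
}

# Stationary renewal train: exponential gaps plus an absolute refractory
# period; the hazard is inflated so the realized rate equals the nominal one
# (mean ISI = refractory + 1/hazard = 1/rate).
.sim_refractory_poisson <- function(rate, duration_s, refractory_s) {
  if (rate * refractory_s >= 1) {
    stop(sprintf("unrealizable train: rate %.3g spk/s with %.3g s refractory period",
                 rate, refractory_s))
  }
  hazard <- rate / (1 - rate * refractory_s)
  times <- numeric(0)
  t_last <- 0
  repeat {
    n <- max(64L, ceiling((duration_s - t_last) * rate * 1.3))
    gaps <- refractory_s + rexp(n, hazard)
    new <- t_last + cumsum(gaps)
    times <- c(times, new)
    t_last <- new[length(new)]
    if (t_last > duration_s) break
  }
  times[times < duration_s]
}

#' Simulate presynaptic (PYR) spike trains
#'
#' One stationary refractory-Poisson train per presynaptic unit, with rates
#' drawn uniformly from `config$presyn_rate_range`.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return Named list of `spike_train`s (ids `PYR01`, `PYR02`, ...).
#' @export
simulate_presyn_trains <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  duration <- sum(config$epoch_durations_s)
  n <- config$n_assemblies * config$presyn_per_assembly
  rates <- runif(n, config$presyn_rate_range[1], config$presyn_rate_range[2])
  trains <- lapply(seq_len(n), function(i) {
    spike_train(sprintf("PYR%02d", i),
                .sim_refractory_poisson(rates[i], duration, config$refractory_s),
                "PYR", shank = ((i - 1L) %% 4L) + 1L)
  })
  names(trains) <- vapply(trains, `[[`, character(1), "unit_id")
  attr(trains, "rates") <- rates
  trains
}

#' Run the closed-loop stimulation rule over trigger spikes
#'
#' Each spike of a trigger unit is detected independently with probability
#' `config$detection_prob`; a detected spike at time t emits a stimulus onset
#' at `t + delay_s` unless that onset falls within
#' `stim_duration_s + dead_time_s` of the previous onset (hardware blanking).
#'
#' @param trains Named list of `spike_train`s.
#' @param trigger_ids Unit ids acting as closed-loop triggers.
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @param interval Optional `c(start, end)` restricting trigger spikes (the
#'   Experience epoch in a full session).
#' @return A `stim_events` object with per-event `trigger_unit`.
#' @export
run_closed_loop <- function(trains, trigger_ids, config, seed = NULL,
                            interval = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(trigger_ids %in% names(trains))) {
    stop("trigger_ids must name units present in 'trains'")
  }
  sp <- lapply(trigger_ids, function(id) {
    tt <- trains[[id]]$times
    if (!is.null(interval)) tt <- restrict(tt, interval)
    data.frame(t = tt, unit = rep(id, length(tt)), stringsAsFactors = FALSE)
  })
  sp <- do.call(rbind, sp)
  if (is.null(sp) || !nrow(sp)) {
    return(stim_events(numeric(0), config$stim_duration_s, config$dead_time_s))
  }
  sp <- sp[order(sp$t), , drop = FALSE]
  detected <- runif(nrow(sp)) < config$detection_prob
  sp <- sp[detected, , drop = FALSE]
  min_gap <- config$stim_duration_s + config$dead_time_s
  onsets <- numeric(nrow(sp))
  units <- character(nrow(sp))
  k <- 0L
  last <- -Inf
  for (i in seq_len(nrow(sp))) {
    cand <- sp$t[i] + config$delay_s
    if (cand - last >= min_gap) {
      k <- k + 1L
      onsets[k] <- cand
      units[k] <- sp$unit[i]
      last <- cand
    }
  }
  stim_events(onsets[seq_len(k)], config$stim_duration_s, config$dead_time_s,
              trigger_unit = units[seq_len(k)])
}

.stim_intervals <- function(events) {
  if (!length(events$onsets)) return(matrix(numeric(0), ncol = 2L))
  cbind(events$onsets, events$onsets + events$duration_s)
}

#' Simulate a postsynaptic (PV) spike train coupled to presynaptic inputs
#'
#' Generates an inhomogeneous Poisson train with rate
#' `base_rate * (g inside stimuli, 1 outside) + sum over presynaptic spikes of
#' k(t - s)`, where the coupling kernel k is a rectangular excess rate on
#' `(kernel_lo_s, kernel_hi_s]` integrating to the pair's transmission
#' probability p. The simulation uses exact Poisson superposition: a
#' homogeneous baseline, extra light-driven spikes inside stimulus intervals
#' (or baseline thinning when g < 1), and Poisson(p) induced spikes per
#' presynaptic spike placed uniformly on the kernel support. The transmission
#' probability switches from `p_before` to `p_after` at the Before/Experience
#' boundary. An absolute refractory period is enforced on the merged train.
#'
#' @param presyn_trains List of presynaptic `spike_train`s converging on the
#'   unit.
#' @param pair_params Data frame (or list) with numeric `p_before` and
#'   `p_after`, one entry per presynaptic train.
#' @param events `stim_events` (may be empty).
#' @param config A [sim_config()].
#' @param base_rate Baseline postsynaptic rate (spk/s).
#' @param epochs `epoch_set` defining the Before/Experience boundary.
#' @param unit_id,shank Identity of the simulated unit.
#' @param seed Optional integer seed.
#' @return A `spike_train`.
#' @export
simulate_postsyn_train <- function(presyn_trains, pair_params, events, config,
                                   base_rate, epochs, unit_id = "PV01",
                                   shank = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p_before <- pair_params$p_before
  p_after <- pair_params$p_after
  if (length(p_before) != length(presyn_trains) ||
      length(p_after) != length(presyn_trains)) {
    stop("pair_params must supply p_before/p_after per presynaptic train")
  }
  duration <- max(epochs$end_s)
  before_end <- epoch_bounds(epochs, "Before")[2]
  g <- config$light_gain

  # homogeneous baseline
  n0 <- rpois(1, base_rate * duration)
  base_sp <- sort(runif(n0, 0, duration))

  # light modulation of the baseline rate inside stimulus intervals
  stim <- .stim_intervals(events)
  if (nrow(stim)) {
    if (g >= 1) {
      extra <- (g - 1) * base_rate * (stim[, 2] - stim[, 1])
      n_ex <- rpois(nrow(stim), extra)
      light_sp <- unlist(lapply(seq_len(nrow(stim)), function(i) {
        runif(n_ex[i], stim[i, 1], stim[i, 2])
      }))
      base_sp <- c(base_sp, light_sp)
    } else {
      inside <- .in_intervals(base_sp, stim)
      drop <- inside & runif(length(base_sp)) > g
      base_sp <- base_sp[!drop]
    }
  }

  # monosynaptically induced spikes: Poisson(p) per presynaptic spike,
  # uniform on the rectangular kernel support
  induced <- lapply(seq_along(presyn_trains), function(j) {
    tp <- presyn_trains[[j]]$times
    if (!length(tp)) return(numeric(0))
    p <- ifelse(tp < before_end, p_before[j], p_after[j])
    n_ind <- rpois(length(tp), p)
    parents <- rep(tp, n_ind)
    parents + runif(length(parents), config$kernel_lo_s, config$kernel_hi_s)
  })

  all_sp <- sort(c(base_sp, unlist(induced)))
  all_sp <- all_sp[all_sp >= 0 & all_sp < duration]
  all_sp <- cpp_enforce_refractory(all_sp, config$refractory_s)
  spike_train(unit_id, all_sp, "PV", shank)
}

.round_times <- function(x) round(x, 6)

#' Generate a full synthetic closed-loop session with ground truth
#'
#' Wires `n_assemblies` converging assemblies (each postsynaptic PV unit
#' receives all of its assembly's presynaptic PYR units), runs the
#' closed-loop stimulation rule on one randomly chosen trigger PYR per
#' assembly during the Experience epoch, applies the light-induced rate gain
#' to the PV units, and injects multiplicative plasticity of the transmission
#' probabilities at the Before/Experience boundary. All spike and event times
#' are rounded to microsecond precision so that written sessions round-trip
#' bit-identically.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the session is fully reproducible given the
#'   seed.
#' @return List with elements `session` (a [session()]) and `ground_truth`
#'   (list with `pairs` and `units` data frames).
#' @export
generate_session <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  durs <- config$epoch_durations_s
  starts <- cumsum(c(0, durs))
  epochs <- epoch_set(names(durs), starts[-length(starts)], starts[-1])
  exp_int <- epoch_bounds(epochs, "Experience")

  presyn <- simulate_presyn_trains(config)
  n_as <- config$n_assemblies
  per <- config$presyn_per_assembly
  assembly_of <- rep(seq_len(n_as), each = per)

  triggers <- unlist(lapply(seq_len(n_as), function(a) {
    ids <- names(presyn)[assembly_of == a]
    sample(ids, min(config$triggers_per_assembly, length(ids)))
  }))

  events <- run_closed_loop(presyn, triggers, config, interval = exp_int)
  keep <- events$onsets + events$duration_s <= exp_int[2]
  events <- stim_events(.round_times(events$onsets[keep]),
                        config$stim_duration_s, config$dead_time_s,
                        events$trigger_unit[keep])

  pr <- config$transmission_prob_range
  factors_assembly <- rep_len(config$plasticity_factors, n_as)
  post_rates <- runif(n_as, config$postsyn_rate_range[1],
                      config$postsyn_rate_range[2])

  pair_rows <- list()
  post_trains <- list()
  for (a in seq_len(n_as)) {
    ids <- names(presyn)[assembly_of == a]
    p_b <- if (pr[1] > 0) {
      exp(runif(length(ids), log(pr[1]), log(pr[2])))
    } else {
      runif(length(ids), pr[1], pr[2])
    }
    fac <- if (config$plasticity_mode == "assembly") {
      rep(factors_assembly[a], length(ids))
    } else {
      fr <- config$pair_factor_range
      exp(runif(length(ids), log(fr[1]), log(fr[2])))
    }
    p_a <- pmin(p_b * fac, 0.99)
    post_id <- sprintf("PV%02d", a)
    tr <- simulate_postsyn_train(presyn[ids],
                                 list(p_before = p_b, p_after = p_a),
                                 events, config, post_rates[a], epochs,
                                 unit_id = post_id,
                                 shank = ((a - 1L) %% 4L) + 1L)
    tr$times <- .round_times(tr$times)
    post_trains[[post_id]] <- tr
    pair_rows[[a]] <- data.frame(
      pre_id = ids, post_id = post_id, assembly = a,
      p_before = p_b, p_after = p_a,
      true_stg_change = log2(p_a / p_b),
      stringsAsFactors = FALSE)
  }

  presyn <- lapply(presyn, function(tr) { tr$times <- .round_times(tr$times); tr })
  ses <- session(c(presyn, post_trains), epochs, events)

  units <- data.frame(unit_id = names(ses$trains),
                      cell_class = vapply(ses$trains, `[[`, character(1),
                                          "cell_class"),
                      is_trigger = names(ses$trains) %in% triggers,
                      stringsAsFactors = FALSE)
  units$realized_cle <- vapply(units$unit_id, function(u) {
    if (!u %in% triggers) return(NA_real_)
    n_sp <- length(restrict(ses$trains[[u]]$times, exp_int))
    if (!n_sp) return(NA_real_)
    sum(events$trigger_unit == u, na.rm = TRUE) / n_sp
  }, numeric(1))
  rownames(units) <- NULL

  list(session = ses,
       ground_truth = list(pairs = do.call(rbind, pair_rows), units = units))
}

#' Simulate a single connected pair over a Before/Experience/After schedule
#'
#' Convenience wrapper used for parameter-recovery and calibration studies:
#' one presynaptic refractory-Poisson train and one coupled postsynaptic
#' train with transmission probability `p_before` (Before epoch) switching to
#' `p_after` (Experience onward), and no light stimulation.
#'
#' @param p_before,p_after Transmission probabilities.
#' @param pre_rate,post_rate Firing rates in spk/s.
#' @param epoch_durations_s Named durations of the Before/Experience/After
#'   epochs in seconds.
#' @param seed Optional integer seed.
#' @param ... Further [sim_config()] overrides.
#' @return List with `pre`, `post` (`spike_train`s) and `epochs`.
#' @export
simulate_pair <- function(p_before, p_after = p_before, pre_rate = 2,
                          post_rate = 10,
                          epoch_durations_s = c(Before = 2700,
                                                Experience = 3300,
                                                After = 2700),
                          seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim_config(n_assemblies = 1L, presyn_per_assembly = 1L,
                    epoch_durations_s = epoch_durations_s, ...)
  durs <- cfg$epoch_durations_s
  starts <- cumsum(c(0, durs))
  epochs <- epoch_set(names(durs), starts[-length(starts)], starts[-1])
  duration <- sum(durs)
  pre <- spike_train("PYR01",
                     .sim_refractory_poisson(pre_rate, duration,
                                             cfg$refractory_s),
                     "PYR", 1L)
  post <- simulate_postsyn_train(list(pre),
                                 list(p_before = p_before, p_after = p_after),
                                 stim_events(numeric(0)), cfg, post_rate,
                                 epochs, unit_id = "PV01", shank = 2L)
  list(pre = pre, post = post, epochs = epochs)
}

#' Simulate a cohort of assembly CCH-difference feature vectors
#'
#' Feature-level generator for classifier calibration and the timing-versus-
#' rate dissociation: produces one CCH-difference-like vector per assembly on
#' a centered 1-ms lag grid, plus a binary STG-change direction label.
#'
#' Regimes:
#' \describe{
#'   \item{`"gain_only"`}{Stimulation changes only the postsynaptic rate: the
#'     difference vector is a flat offset (positive for increases, negative
#'     for decreases) plus noise. All class information is co-firing ("rate")
#'     information: Z-scoring each vector removes it, shuffling the bin order
#'     preserves it.}
#'   \item{`"latency"`}{Stimulation restructures spike timing at constant
#'     rate: a localized bump whose lag sign depends on the class, with no
#'     class difference in the mean. All class information is millisecond
#'     timing: Z-scoring preserves it, bin shuffling destroys it.}
#' }
#'
#' @param n Number of assemblies (default 122).
#' @param regime `"gain_only"` or `"latency"`.
#' @param lags_ms Integer lag grid in ms (default -50:50).
#' @param offset_delta,offset_sd Gain-only class offset mean and SD (spk/s).
#' @param bump_amp,bump_sd_ms,bump_lag_ms Latency bump amplitude, width and
#'   center magnitude.
#' @param noise_sd Additive white noise SD per bin.
#' @param seed Optional integer seed.
#' @return List with `features` (n x length(lags_ms) matrix), `labels`
#'   (factor `decrease`/`increase`) and `lags_s`.
#' @export
simulate_assembly_features <- function(n = 122L,
                                       regime = c("gain_only", "latency"),
                                       lags_ms = -50:50, offset_delta = 1,
                                       offset_sd = 0.5, bump_amp = 2,
                                       bump_sd_ms = 2, bump_lag_ms = 3,
                                       noise_sd = 1, seed = NULL) {
  regime <- match.arg(regime)
  if (!is.null(seed)) set.seed(seed)
  labels <- factor(sample(rep(c("decrease", "increase"), length.out = n)),
                   levels = c("decrease", "increase"))
  X <- matrix(rnorm(n * length(lags_ms), sd = noise_sd), n, length(lags_ms))
  up <- labels == "increase"
  if (regime == "gain_only") {
    offs <- ifelse(up, 1, -1) * offset_delta + rnorm(n, sd = offset_sd)
    X <- X + offs
  } else {
    amp <- bump_amp * (1 + 0.15 * rnorm(n))
    for (i in seq_len(n)) {
      ctr <- if (up[i]) bump_lag_ms else -bump_lag_ms
      X[i, ] <- X[i, ] + amp[i] * exp(-(lags_ms - ctr)^2 / (2 * bump_sd_ms^2))
    }
  }
  colnames(X) <- sprintf("lag_%+04d", lags_ms)
  list(features = X, labels = labels, lags_s = lags_ms / 1000)
}
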