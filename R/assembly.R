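## Converging assemblies: construction, peer/non-peer statistics,
## CCH-difference spike-timing features, sham assemblies and the
## rank-correlation permutation test.

.pair_id <- function(pre_id, post_id) paste(pre_id, post_id, sep = ":")

#' Group eligible pairs into converging assemblies
#'
#' A converging assembly (CA) is one postsynaptic unit together with all
#' eligible presynaptic units connected to it. The pairs are partitioned:
#' every eligible pair belongs to exactly one assembly.
#'
#' @param pairs Data frame with `pre_id` and `post_id` columns (and
#'   optionally `eligible`; when present only eligible rows are used).
#' @return Named list of assemblies, each a list with `post_id`, `pre_ids`
#'   and `pair_ids`.
#' @export
build_assemblies <- function(pairs) {
  if ("eligible" %in% names(pairs)) pairs <- pairs[pairs$eligible, , drop = FALSE]
  if (!nrow(pairs)) return(structure(list(), names = character(0)))
  out <- lapply(split(pairs, pairs$post_id), function(df) {
    list(post_id = df$post_id[1L], pre_ids = df$pre_id,
         pair_ids = .pair_id(df$pre_id, df$post_id))
  })
  out[order(names(out))]
}

#' Peer and non-peer means of a per-pair statistic
#'
#' For a given pair, the peer mean is the mean of the statistic over the
#' other pairs of the same assembly; the non-peer mean is the mean over all
#' pairs of the other simultaneously recorded assemblies. Either mean is
#' `NA` when the respective set is empty.
#'
#' @param pair_id Pair identifier (`"pre:post"`).
#' @param assemblies Assemblies from [build_assemblies()].
#' @param values Named numeric vector of the statistic, keyed by pair id.
#' @return Named numeric `c(mean_peer, mean_nonpeer)`.
#' @export
peer_nonpeer_means <- function(pair_id, assemblies, values) {
  holds <- vapply(assemblies, function(a) pair_id %in% a$pair_ids, logical(1))
  if (!any(holds)) stop("pair '", pair_id, "' not found in any assembly")
  own <- assemblies[[which(holds)[1L]]]
  peers <- setdiff(own$pair_ids, pair_id)
  nonpeers <- unlist(lapply(assemblies[!holds], `[[`, "pair_ids"))
  mp <- if (length(peers)) mean(values[peers], na.rm = TRUE) else NA_real_
  mn <- if (length(nonpeers)) mean(values[nonpeers], na.rm = TRUE) else NA_real_
  c(mean_peer = mp, mean_nonpeer = mn)
}

#' CCH difference of a pair between stimulated and unstimulated periods
#'
#' Conditional-rate CCH of the pair computed with presynaptic reference
#' spikes restricted to the stimulus intervals `[onset, onset + duration)`,
#' minus the CCH with reference spikes restricted to the between-stimulus
#' periods of the Experience epoch. The difference isolates the effect of
#' the stimuli on the pair's joint spike timing; slow excitability changes
#' common to both periods cancel. Computed on a centered 1-ms lag grid so
#' that a window of half-width W ms slices to 2W + 1 elements.
#'
#' @param pre,post `spike_train`s.
#' @param events `stim_events` (non-empty).
#' @param experience `c(start, end)` bounds of the Experience epoch.
#' @param bin_width_s Bin width (default 1 ms).
#' @param window_s Lag half-window (default 50 ms).
#' @return Object of class `cch_difference` with `pair_id`, `lags`,
#'   `stim_rate`, `between_rate`, `difference` and a `missing` flag set when
#'   one interval set holds no reference spikes.
#' @export
cch_difference <- function(pre, post, events, experience,
                           bin_width_s = 0.001, window_s = 0.050) {
  if (!inherits(events, "stim_events") || !length(events$onsets)) {
    stop("events must be a non-empty stim_events object")
  }
  stim <- .stim_intervals(events)
  stim[, 1] <- pmax(stim[, 1], experience[1])
  stim[, 2] <- pmin(stim[, 2], experience[2])
  between <- interval_complement(stim, experience)
  pre_stim <- restrict(pre, stim)
  pre_btw <- restrict(pre, between)
  pid <- .pair_id(.unit_id(pre, "pre"), .unit_id(post, "post"))
  grid <- .make_grid(bin_width_s, window_s, "center")
  if (!n_spikes(pre_stim) || !n_spikes(pre_btw)) {
    nb <- grid$n_bins
    return(structure(list(pair_id = pid, lags = grid$centers,
                          stim_rate = rep(NA_real_, nb),
                          between_rate = rep(NA_real_, nb),
                          difference = rep(NA_real_, nb), missing = TRUE),
                     class = "cch_difference"))
  }
  cch_s <- compute_cch(pre_stim, post, bin_width_s, window_s,
                       align = "center", exclude_self = FALSE)
  cch_b <- compute_cch(pre_btw, post, bin_width_s, window_s,
                       align = "center", exclude_self = FALSE)
  structure(
    list(pair_id = pid, lags = cch_s$lags, stim_rate = cch_s$rate,
         between_rate = cch_b$rate, difference = cch_s$rate - cch_b$rate,
         missing = FALSE),
    class = "cch_difference"
  )
}

#' Aggregate CCH differences over an assembly
#'
#' Element-wise sum of the member pairs' CCH-difference vectors, either over
#' the whole assembly or over the peers of one pair (all members except that
#' pair). Members flagged missing are skipped.
#'
#' @param assembly One assembly from [build_assemblies()].
#' @param pair_diffs Named list of `cch_difference` objects keyed by pair id.
#' @param mode `"whole_assembly"` or `"peers_of"`.
#' @param pair_id The reference pair when `mode = "peers_of"`.
#' @return Numeric vector (summed difference, spk/s).
#' @export
aggregate_cch_difference <- function(assembly, pair_diffs,
                                     mode = c("whole_assembly", "peers_of"),
                                     pair_id = NULL) {
  mode <- match.arg(mode)
  ids <- assembly$pair_ids
  if (mode == "peers_of") {
    if (is.null(pair_id)) stop("pair_id required for mode 'peers_of'")
    ids <- setdiff(ids, pair_id)
  }
  ids <- ids[ids %in% names(pair_diffs)]
  ids <- ids[!vapply(pair_diffs[ids], `[[`, logical(1), "missing")]
  if (!length(ids)) stop("no usable member CCH differences to aggregate")
  Reduce(`+`, lapply(pair_diffs[ids], `[[`, "difference"))
}

#' Sham assemblies by random reallocation of pairs
#'
#' Randomly partitions the session's pairs into assemblies whose size
#' multiset matches the observed one, destroying the true pair-to-assembly
#' allocation while preserving the assembly-size structure.
#'
#' @param pair_ids Character vector of the session's pair ids.
#' @param sizes Integer vector of assembly sizes; must sum to
#'   `length(pair_ids)`.
#' @param seed Optional integer seed.
#' @return Named list of sham assemblies (same structure as
#'   [build_assemblies()]).
#' @export
sham_assemblies <- function(pair_ids, sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sum(sizes) != length(pair_ids)) {
    stop("assembly sizes must sum to the number of pairs")
  }
  perm <- sample(pair_ids)
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  out <- lapply(seq_along(sizes), function(k) {
    ids <- perm[starts[k]:stops[k]]
    list(post_id = sprintf("sham%02d", k),
         pre_ids = sub(":.*$", "", ids), pair_ids = ids)
  })
  names(out) <- vapply(out, `[[`, character(1), "post_id")
  out
}

#' Spearman rank correlation with a permutation test
#'
#' Rank correlation coefficient between two vectors, with a two-tailed
#' p-value from random pairings (the +1/(n_perm + 1) correction applied).
#' Rows with missing values are dropped.
#'
#' @param x,y Numeric vectors of equal length (n >= 3 after NA removal).
#' @param n_perm Number of permutations (default 2000).
#' @param seed Optional integer seed.
#' @return List with `cc`, `p`, `n`, `n_perm`. `cc` is `NA` (flagged with a
#'   warning) when either vector is constant.
#' @export
spearman_permutation <- function(x, y, n_perm = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: rank correlation undefined")
    return(list(cc = NA_real_, p = NA_real_, n = n, n_perm = n_perm))
  }
  cc <- cor(x, y, method = "spearman")
  rx <- rank(x)
  ry <- rank(y)
  nullcc <- vapply(seq_len(n_perm), function(i) {
    cor(rx, sample(ry), method = "pearson")
  }, numeric(1))
  p <- (1 + sum(abs(nullcc) >= abs(cc))) / (n_perm + 1)
  list(cc = cc, p = p, n = n, n_perm = n_perm)
}
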