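## Cross-validated regression and classification of STG changes, the
## timing/rate feature manipulations, and virtual closed-loop construction.

#' Z-score a vector
#'
#' Centers and scales to mean 0, SD 1. Z-scoring a CCH-difference vector
#' removes its co-firing ("rate") information while preserving the relative
#' timing structure.
#'
#' @param v Numeric vector, length >= 2.
#' @return The standardized vector; all-`NA` (with a warning) when `v` is
#'   constant.
#' @export
zscore_vector <- function(v) {
  if (length(v) < 2L) stop("need at least 2 elements")
  s <- sd(v)
  if (!is.finite(s) || s == 0) {
    warning("constant vector: z-score undefined")
    return(rep(NA_real_, length(v)))
  }
  (v - mean(v)) / s
}

#' Randomly permute the bins of a vector
#'
#' Destroys the temporal ordering of a CCH-difference vector while preserving
#' its value multiset, removing precise-timing information but keeping
#' co-firing (rate) information.
#'
#' @param v Numeric vector.
#' @param seed Optional integer seed.
#' @return Permuted vector.
#' @export
shuffle_bins <- function(v, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v[sample.int(length(v))]
}

## ------------------------------------------------------------------
## internals shared by the cross-validation drivers

# area under the ROC curve from scores, by the rank (Mann-Whitney) identity
.auc <- function(scores, positive) {
  np <- sum(positive)
  nn <- sum(!positive)
  if (!np || !nn) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

.scale_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

.scale_apply <- function(x, sc) {
  sweep(sweep(x, 2L, sc$mu, "-"), 2L, sc$sd, "/")
}

# RBF kernel width by the median heuristic of pairwise distances on the
# (scaled) training features
.median_gamma <- function(x, max_rows = 400L) {
  if (nrow(x) > max_rows) x <- x[sample.int(nrow(x), max_rows), , drop = FALSE]
  d2 <- as.numeric(stats::dist(x))^2
  m <- median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) 1 / max(1L, ncol(x)) else 1 / m
}

.fold_assignment <- function(n, folds) sample(rep_len(seq_len(folds), n))

# assemblies are assigned whole to folds: no assembly spans train and test
.assembly_folds <- function(assembly_ids, folds) {
  ids <- unique(assembly_ids)
  af <- sample(rep_len(seq_len(folds), length(ids)))
  af[match(assembly_ids, ids)]
}

.folds_ok <- function(fold, y, folds) {
  all(vapply(seq_len(folds), function(f) {
    tr <- y[fold != f]
    length(unique(tr)) == 2L && sum(fold == f) > 0L
  }, logical(1)))
}

# linear SVM decision scores for the second factor level, pooled out-of-fold
.oof_svm_scores <- function(x, y, fold, folds, cost) {
  pos <- levels(y)[2L]
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    sc <- .scale_fit(x[tr, , drop = FALSE])
    xt <- .scale_apply(x[tr, , drop = FALSE], sc)
    fit <- e1071::svm(xt, y[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    pr <- predict(fit, .scale_apply(x[!tr, , drop = FALSE], sc),
                  decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    lev1 <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
    scores[!tr] <- if (lev1 == pos) dv[, 1L] else -dv[, 1L]
  }
  scores
}

#' Cross-validated support-vector regression
#'
#' RBF-kernel SVR with k-fold cross-validation repeated many times; per
#' repeat, out-of-fold predictions are pooled and the reconstruction
#' coefficient of determination (R^2) is computed once. Features are
#' standardized on the training folds only; the kernel width follows the
#' median heuristic of pairwise training distances.
#'
#' @param features Numeric matrix or data frame (rows = observations).
#' @param target Numeric response.
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeated random partitions (default 100).
#' @param seed Optional integer seed.
#' @param cost SVR cost parameter (default 1).
#' @return Numeric vector of R^2 values, one per repeat.
#' @export
crossval_svr <- function(features, target, folds = 5, repeats = 100,
                         seed = NULL, cost = 1) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(features)
  y <- as.numeric(target)
  if (nrow(x) < folds) stop("need at least as many rows as folds")
  if (sd(y) == 0) stop("degenerate target: zero variance")
  ss_tot <- sum((y - mean(y))^2)
  vapply(seq_len(repeats), function(r) {
    fold <- .fold_assignment(nrow(x), folds)
    pred <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f
      sc <- .scale_fit(x[tr, , drop = FALSE])
      xt <- .scale_apply(x[tr, , drop = FALSE], sc)
      fit <- e1071::svm(xt, y[tr], kernel = "radial", cost = cost,
                        gamma = .median_gamma(xt), scale = FALSE)
      pred[!tr] <- predict(fit, .scale_apply(x[!tr, , drop = FALSE], sc))
    }
    1 - sum((y - pred)^2) / ss_tot
  }, numeric(1))
}

#' Cross-validated linear-SVM classification (AUC)
#'
#' Linear SVM with k-fold cross-validation repeated many times; per repeat,
#' the out-of-fold decision values are pooled and the area under the ROC
#' curve computed. Three fold schemes are available: `"random"` (row-level
#' folds), `"entire_assembly"` (folds partition whole assemblies, so pairs
#' of one assembly are never split between training and testing) and
#' `"subsample_one_per_assembly"` (one pair drawn per assembly per round,
#' rounds repeated until every pair has at least `repeats` out-of-fold
#' predictions, of which `repeats` are kept per pair; the r-th AUC pools the
#' r-th prediction of every pair).
#'
#' @param features Numeric matrix or data frame.
#' @param labels Two-level factor (or coercible).
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeats / kept predictions (default 100).
#' @param seed Optional integer seed.
#' @param scheme Fold scheme (see above).
#' @param assembly_ids Assembly membership per row; required by the
#'   assembly-aware schemes.
#' @param cost SVM cost parameter (default 1).
#' @param max_redraws Maximum partition redraws when a training fold misses
#'   a class (default 100).
#' @return Numeric vector of AUC values, one per repeat.
#' @export
crossval_svm_auc <- function(features, labels, folds = 5, repeats = 100,
                             seed = NULL,
                             scheme = c("random", "entire_assembly",
                                        "subsample_one_per_assembly"),
                             assembly_ids = NULL, cost = 1,
                             max_redraws = 100) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("labels must have exactly two classes")
  if (scheme != "random" && is.null(assembly_ids)) {
    stop("assembly_ids required for scheme '", scheme, "'")
  }
  pos <- levels(y)[2L] == y

  draw_folds <- function(idx) {
    for (try in seq_len(max_redraws)) {
      fold <- if (scheme == "entire_assembly") {
        .assembly_folds(assembly_ids[idx], folds)
      } else {
        .fold_assignment(length(idx), folds)
      }
      if (.folds_ok(fold, y[idx], folds)) return(fold)
    }
    stop("could not draw a fold partition with both classes in every training set")
  }

  if (scheme == "subsample_one_per_assembly") {
    n <- nrow(x)
    preds <- vector("list", n)
    while (min(lengths(preds)) < repeats) {
      idx <- vapply(split(seq_len(n), assembly_ids), function(rows) {
        if (length(rows) == 1L) rows else sample(rows, 1L)
      }, integer(1))
      fold <- draw_folds(idx)
      sc <- .oof_svm_scores(x[idx, , drop = FALSE], droplevels(y[idx]),
                            fold, folds, cost)
      for (k in seq_along(idx)) {
        preds[[idx[k]]] <- c(preds[[idx[k]]], sc[k])
      }
    }
    kept <- t(vapply(preds, function(p) p[sample.int(length(p), repeats)],
                     numeric(repeats)))
    return(vapply(seq_len(repeats), function(r) .auc(kept[, r], pos),
                  numeric(1)))
  }

  vapply(seq_len(repeats), function(r) {
    fold <- draw_folds(seq_len(nrow(x)))
    sc <- .oof_svm_scores(x, y, fold, folds, cost)
    .auc(sc, pos)
  }, numeric(1))
}

#' Classifier performance across CCH-difference window sizes or offsets
#'
#' Slices the CCH-difference feature matrix either to windows of increasing
#' half-width centered at zero lag, or to a sliding window of fixed width at
#' different lag offsets, and runs [crossval_svm_auc()] on each slice.
#'
#' @param diff_matrix Numeric matrix, columns = lag bins.
#' @param lags_s Numeric lag centers (seconds), one per column.
#' @param labels Two-level class labels.
#' @param half_widths_s Window half-widths to scan (centered windows).
#' @param offsets_s Window-center offsets to scan (sliding window).
#' @param offset_half_width_s Half-width of the sliding window (default
#'   10 ms, i.e. a 21-element window on a 1-ms centered grid).
#' @param folds,repeats,seed,cost Passed to [crossval_svm_auc()].
#' @return Data frame with one row per setting: `setting`, `value_s`,
#'   `n_bins`, `mean_auc`, `sd_auc`.
#' @export
window_scan <- function(diff_matrix, lags_s, labels, half_widths_s = NULL,
                        offsets_s = NULL, offset_half_width_s = 0.010,
                        folds = 5, repeats = 20, seed = NULL, cost = 1) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(diff_matrix)
  if (length(lags_s) != ncol(x)) stop("lags_s must match the columns")
  if (is.null(half_widths_s) && is.null(offsets_s)) {
    stop("supply half_widths_s and/or offsets_s")
  }
  tol <- 1e-9
  settings <- list()
  if (!is.null(half_widths_s)) {
    for (w in half_widths_s) {
      settings[[length(settings) + 1L]] <-
        list(setting = "half_width", value = w,
             cols = which(abs(lags_s) <= w + tol))
    }
  }
  if (!is.null(offsets_s)) {
    for (o in offsets_s) {
      settings[[length(settings) + 1L]] <-
        list(setting = "offset", value = o,
             cols = which(abs(lags_s - o) <= offset_half_width_s + tol))
    }
  }
  rows <- lapply(settings, function(s) {
    if (!length(s$cols)) stop("window outside the stored lag range")
    aucs <- crossval_svm_auc(x[, s$cols, drop = FALSE], labels, folds,
                             repeats, cost = cost)
    data.frame(setting = s$setting, value_s = s$value,
               n_bins = length(s$cols), mean_auc = mean(aucs),
               sd_auc = sd(aucs), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default closed-loop-efficiency sampler for virtual experiments
#'
#' Log-normal CLE distribution matched to the trigger-unit quantiles observed
#' in real closed-loop sessions (median 0.054, IQR 0.013-0.184), truncated
#' to (0, 1].
#'
#' @param n Number of draws.
#' @return Numeric CLE draws.
#' @export
rlnorm_cle <- function(n) {
  pmin(rlnorm(n, meanlog = log(0.054), sdlog = 1.963), 1)
}

#' Virtual closed-loop stimulation of an unstimulated session
#'
#' Assigns sham stimulation periods to a stimulus-free (control) session:
#' for each assembly, one presynaptic unit is chosen at random as the virtual
#' trigger, a CLE value is drawn from `cle_distribution`, and that fraction
#' of the unit's Experience-epoch spikes is selected at random as virtual
#' trigger spikes. Onsets follow each selected spike by `delay_s`, with the
#' stimulus-duration + dead-time blanking rule applied across all virtual
#' triggers. No spikes are altered.
#'
#' @param session A [session()] with no real events.
#' @param assemblies Assemblies from [build_assemblies()] (the per-assembly
#'   trigger pool).
#' @param cle_distribution Function of `n` returning CLE draws (default
#'   [rlnorm_cle()]).
#' @param delay_s,stim_duration_s,dead_time_s Stimulation timing parameters
#'   (defaults 3 / 30 / 20 ms).
#' @param seed Optional integer seed.
#' @return A `stim_events` object; the drawn CLEs and trigger units are
#'   attached as attributes `drawn_cle` and `trigger_ids`.
#' @export
virtual_closed_loop <- function(session, assemblies,
                                cle_distribution = rlnorm_cle,
                                delay_s = 0.003, stim_duration_s = 0.030,
                                dead_time_s = 0.020, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(session$events$onsets)) {
    stop("virtual closed loop requires a session without real events")
  }
  ex <- epoch_bounds(session$epochs, "Experience")
  cand <- NULL
  trig_ids <- character(0)
  cles <- numeric(0)
  for (a in assemblies) {
    unit <- if (length(a$pre_ids) == 1L) a$pre_ids else sample(a$pre_ids, 1L)
    cle <- cle_distribution(1L)
    sp <- restrict(session$trains[[unit]]$times, ex)
    if (!length(sp)) stop("no Experience-epoch spikes for unit '", unit, "'")
    k <- round(cle * length(sp))
    if (k > 0L) {
      chosen <- sort(sample(sp, k))
      cand <- rbind(cand, cbind(chosen + delay_s, match(unit, names(session$trains))))
    }
    trig_ids <- c(trig_ids, unit)
    cles <- c(cles, cle)
  }
  if (is.null(cand) || !nrow(cand)) {
    ev <- stim_events(numeric(0), stim_duration_s, dead_time_s)
  } else {
    cand <- cand[order(cand[, 1]), , drop = FALSE]
    min_gap <- stim_duration_s + dead_time_s
    keep_on <- numeric(nrow(cand))
    keep_unit <- character(nrow(cand))
    k <- 0L
    last <- -Inf
    for (i in seq_len(nrow(cand))) {
      if (cand[i, 1] - last >= min_gap &&
          cand[i, 1] + stim_duration_s <= ex[2]) {
        k <- k + 1L
        keep_on[k] <- cand[i, 1]
        keep_unit[k] <- names(session$trains)[cand[i, 2]]
        last <- cand[i, 1]
      }
    }
    ev <- stim_events(keep_on[seq_len(k)], stim_duration_s, dead_time_s,
                      keep_unit[seq_len(k)])
  }
  attr(ev, "drawn_cle") <- stats::setNames(cles, trig_ids)
  attr(ev, "trigger_ids") <- trig_ids
  ev
}
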