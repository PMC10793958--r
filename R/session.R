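#' @useDynLib spiketrans, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rexp rpois runif rlnorm sd cor ppois dpois
#'   rbinom quantile wilcox.test rnorm predict
#' @importFrom utils read.delim write.table modifyList head
NULL

.CELL_CLASSES <- c("PYR", "PV", "OTHER")

#' Construct a spike train
#'
#' A spike train is a single unit's sorted spike times (in seconds) together
#' with its identity metadata: unit id, putative cell class and recording
#' shank.
#'
#' @param unit_id Character scalar, unique unit identifier.
#' @param times Numeric vector of spike times in seconds; must be
#'   non-negative, finite and strictly increasing.
#' @param cell_class One of `"PYR"`, `"PV"`, `"OTHER"`.
#' @param shank Integer shank number (>= 1).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(unit_id, times, cell_class = "OTHER", shank = 1L) {
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) {
    stop("spike times contain NA/non-finite values for unit '", unit_id, "'")
  }
  if (length(times) && times[1] < 0) {
    stop("negative spike times for unit '", unit_id, "'")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("spike times not strictly increasing for unit '", unit_id, "'")
  }
  cell_class <- match.arg(toupper(as.character(cell_class)), .CELL_CLASSES)
  shank <- as.integer(shank)
  if (is.na(shank) || shank < 1L) stop("shank must be an integer >= 1")
  structure(
    list(unit_id = as.character(unit_id), times = times,
         cell_class = cell_class, shank = shank),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s (%s, shank %d): %d spikes",
              x$unit_id, x$cell_class, x$shank, length(x$times)))
  if (length(x$times)) {
    cat(sprintf(" over [%.3f, %.3f] s", x$times[1], x$times[length(x$times)]))
  }
  cat("\n")
  invisible(x)
}

#' Number of spikes in a train
#' @param x A `spike_train`.
#' @return Integer spike count.
#' @export
n_spikes <- function(x) {
  length(if (inherits(x, "spike_train")) x$times else x)
}

.spike_times <- function(x) {
  if (inherits(x, "spike_train")) x$times else as.numeric(x)
}

.unit_id <- function(x, default = "") {
  if (inherits(x, "spike_train")) x$unit_id else default
}

#' Construct an epoch set
#'
#' Labeled, non-overlapping half-open intervals `[start, end)` partitioning a
#' session into analysis epochs. When the canonical labels Before, Experience
#' and After are present they must occur in that temporal order.
#'
#' @param label Character vector of epoch labels.
#' @param start_s,end_s Numeric vectors of interval bounds in seconds.
#' @return An object of class `epoch_set` (a data frame with columns
#'   `label`, `start_s`, `end_s`), ordered by start time.
#' @export
epoch_set <- function(label, start_s, end_s) {
  df <- data.frame(label = as.character(label),
                   start_s = as.numeric(start_s),
                   end_s = as.numeric(end_s),
                   stringsAsFactors = FALSE)
  if (anyNA(df)) stop("epoch table contains NA values")
  if (any(df$end_s <= df$start_s)) stop("epoch end must exceed epoch start")
  if (anyDuplicated(df$label)) stop("duplicated epoch labels")
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1L && any(df$start_s[-1L] < df$end_s[-nrow(df)])) {
    stop("epochs overlap")
  }
  canon <- c("Before", "Experience", "After")
  pos <- match(canon, df$label)
  pos <- pos[!is.na(pos)]
  if (length(pos) > 1L && is.unsorted(pos, strictly = TRUE)) {
    stop("epochs must be ordered Before < Experience < After")
  }
  structure(df, class = c("epoch_set", "data.frame"))
}

#' Bounds of a named epoch
#' @param epochs An `epoch_set`.
#' @param label Epoch label to look up.
#' @return Numeric `c(start_s, end_s)`.
#' @export
epoch_bounds <- function(epochs, label) {
  i <- match(label, epochs$label)
  if (is.na(i)) stop("no epoch labeled '", label, "'")
  c(epochs$start_s[i], epochs$end_s[i])
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Construct a stimulus-event series
#'
#' Light-stimulus onsets with a common duration. Consecutive onsets must be
#' separated by at least `duration_s + dead_time_s`, mirroring the hardware
#' constraint that no stimulus can be triggered during an ongoing stimulus or
#' its post-stimulus dead time.
#'
#' @param onsets Strictly increasing numeric vector of onset times (s).
#' @param duration_s Stimulus duration in seconds (default 30 ms).
#' @param dead_time_s Post-stimulus dead time in seconds (default 20 ms).
#' @param trigger_unit Optional character vector (one per event) naming the
#'   unit whose spike triggered the stimulus; `NA` where unknown.
#' @return An object of class `stim_events`.
#' @export
stim_events <- function(onsets, duration_s = 0.030, dead_time_s = 0.020,
                        trigger_unit = NULL) {
  onsets <- as.numeric(onsets)
  if (anyNA(onsets)) stop("event onsets contain NA")
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop("event onsets not strictly increasing")
  }
  min_gap <- duration_s + dead_time_s
  if (length(onsets) > 1L) {
    gaps <- diff(onsets)
    bad <- which(gaps < min_gap - 1e-12)
    if (length(bad)) {
      stop(sprintf(
        "events %d and %d are %.4f s apart; minimum spacing is %.4f s (duration + dead time)",
        bad[1L], bad[1L] + 1L, gaps[bad[1L]], min_gap))
    }
  }
  if (is.null(trigger_unit)) {
    trigger_unit <- rep(NA_character_, length(onsets))
  } else {
    trigger_unit <- as.character(trigger_unit)
    if (length(trigger_unit) != length(onsets)) {
      stop("trigger_unit must have one entry per event")
    }
  }
  structure(
    list(onsets = onsets, duration_s = duration_s, dead_time_s = dead_time_s,
         trigger_unit = trigger_unit),
    class = "stim_events"
  )
}

#' Number of stimulus events
#' @param events A `stim_events` object.
#' @return Integer event count.
#' @export
n_events <- function(events) length(events$onsets)

#' @export
print.stim_events <- function(x, ...) {
  cat(sprintf("<stim_events> %d events, duration %.0f ms, dead time %.0f ms\n",
              length(x$onsets), 1000 * x$duration_s, 1000 * x$dead_time_s))
  invisible(x)
}

#' Assemble a recording session
#'
#' Bundles spike trains, an epoch set and (possibly empty) stimulus events
#' into a validated session object. Unit ids must be unique, all spike times
#' must fall within the session duration, and events must fall inside the
#' Experience epoch.
#'
#' @param trains List of `spike_train` objects.
#' @param epochs An `epoch_set`.
#' @param events A `stim_events` object, or `NULL` for a stimulus-free session.
#' @param duration_s Session duration in seconds; defaults to the latest epoch
#'   end or spike time.
#' @return An object of class `session`.
#' @export
session <- function(trains, epochs, events = NULL, duration_s = NULL) {
  if (!length(trains)) stop("session needs at least one spike train")
  if (!all(vapply(trains, inherits, logical(1), "spike_train"))) {
    stop("all trains must be spike_train objects")
  }
  ids <- vapply(trains, `[[`, character(1), "unit_id")
  if (anyDuplicated(ids)) stop("duplicated unit ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(trains) <- ids
  if (!inherits(epochs, "epoch_set")) stop("epochs must be an epoch_set")
  if (is.null(events)) events <- stim_events(numeric(0))
  if (!inherits(events, "stim_events")) stop("events must be stim_events")
  last_spike <- suppressWarnings(max(vapply(trains, function(tr) {
    if (length(tr$times)) tr$times[length(tr$times)] else 0
  }, numeric(1))))
  if (is.null(duration_s)) duration_s <- max(epochs$end_s, last_spike)
  if (last_spike > duration_s + 1e-9) {
    stop("spike times exceed the session duration")
  }
  if (length(events$onsets)) {
    if (!"Experience" %in% epochs$label) {
      stop("sessions with events need an Experience epoch")
    }
    ex <- epoch_bounds(epochs, "Experience")
    if (any(events$onsets < ex[1] - 1e-9) ||
        any(events$onsets + events$duration_s > ex[2] + 1e-9)) {
      stop("stimulus events must fall inside the Experience epoch")
    }
  }
  structure(
    list(trains = trains, epochs = epochs, events = events,
         duration_s = duration_s),
    class = "session"
  )
}

#' @export
print.session <- function(x, ...) {
  cls <- table(vapply(x$trains, `[[`, character(1), "cell_class"))
  cat(sprintf("<session> %d units (%s), %.1f min, %d events\n",
              length(x$trains),
              paste(sprintf("%s: %d", names(cls), as.integer(cls)),
                    collapse = ", "),
              x$duration_s / 60, length(x$events$onsets)))
  print(x$epochs)
  invisible(x)
}

#' Unit ids of a given cell class
#' @param session A `session`.
#' @param cell_class Class to select (`"PYR"`, `"PV"`, `"OTHER"`).
#' @return Character vector of unit ids.
#' @export
units_of_class <- function(session, cell_class) {
  ids <- names(session$trains)
  cls <- vapply(session$trains, `[[`, character(1), "cell_class")
  ids[cls == cell_class]
}

## ------------------------------------------------------------------
## interval utilities

.as_intervals <- function(x) {
  if (inherits(x, "epoch_set")) {
    m <- cbind(x$start_s, x$end_s)
  } else if (is.matrix(x)) {
    m <- x[, 1:2, drop = FALSE]
  } else if (is.data.frame(x)) {
    m <- cbind(x[[1]], x[[2]])
  } else if (is.numeric(x) && length(x) == 2L) {
    m <- matrix(x, nrow = 1L)
  } else {
    stop("cannot interpret 'intervals'")
  }
  storage.mode(m) <- "double"
  if (nrow(m) && any(m[, 2] < m[, 1])) stop("interval end precedes start")
  m
}

.in_intervals <- function(t, intervals) {
  m <- .as_intervals(intervals)
  keep <- rep(FALSE, length(t))
  for (i in seq_len(nrow(m))) {
    keep <- keep | (t >= m[i, 1] & t < m[i, 2])
  }
  keep
}

#' Total length of an interval set
#' @param intervals Interval specification (two-column matrix, data frame,
#'   `c(start, end)` pair, or `epoch_set`).
#' @return Total length in seconds.
#' @export
interval_total <- function(intervals) {
  m <- .as_intervals(intervals)
  sum(m[, 2] - m[, 1])
}

#' Complement of an interval set within a spanning interval
#'
#' Used, e.g., to derive the between-stimulus periods of the Experience epoch
#' from the stimulus intervals.
#'
#' @param intervals Interval set to remove (assumed non-overlapping).
#' @param within Numeric `c(start, end)` spanning interval.
#' @return Two-column matrix of the remaining half-open intervals.
#' @export
interval_complement <- function(intervals, within) {
  m <- .as_intervals(intervals)
  m <- m[order(m[, 1]), , drop = FALSE]
  lo <- within[1]
  out <- NULL
  for (i in seq_len(nrow(m))) {
    s <- max(m[i, 1], within[1])
    e <- min(m[i, 2], within[2])
    if (e <= s) next
    if (s > lo) out <- rbind(out, c(lo, s))
    lo <- max(lo, e)
  }
  if (lo < within[2]) out <- rbind(out, c(lo, within[2]))
  if (is.null(out)) out <- matrix(numeric(0), ncol = 2L)
  out
}

#' Restrict spike times or events to an interval set
#'
#' Keeps only items whose time lies in the union of half-open intervals
#' `[start, end)`; ordering is preserved and an empty result is allowed.
#' `restrict` is idempotent and never adds items.
#'
#' @param x A `spike_train`, `stim_events` object or numeric time vector.
#' @param intervals Interval specification (see [interval_total()]).
#' @return Object of the same type as `x`.
#' @export
restrict <- function(x, intervals) UseMethod("restrict")

#' @export
restrict.default <- function(x, intervals) {
  x[.in_intervals(as.numeric(x), intervals)]
}

#' @export
restrict.spike_train <- function(x, intervals) {
  x$times <- x$times[.in_intervals(x$times, intervals)]
  x
}

#' @export
restrict.stim_events <- function(x, intervals) {
  keep <- .in_intervals(x$onsets, intervals)
  x$onsets <- x$onsets[keep]
  x$trigger_unit <- x$trigger_unit[keep]
  x
}

## ------------------------------------------------------------------
## delimited-text IO

.read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   stringsAsFactors = FALSE, na.strings = NULL,
                   check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("file '%s': missing column(s) %s", path,
                 paste(sQuote(missing), collapse = ", ")))
  }
  df
}

.parse_numeric_col <- function(df, col, path) {
  x <- df[[col]]
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad)) {
    stop(sprintf("file '%s', line %d, field '%s': cannot parse value '%s'",
                 path, bad[1L] + 1L, col, x[bad[1L]]))
  }
  out
}

#' Read a session from delimited-text files
#'
#' Reads the three tab-separated tables that define a session: `spikes.tsv`
#' (`unit_id`, `time_s`, `cell_class`, `shank`; one spike per row),
#' `epochs.tsv` (`label`, `start_s`, `end_s`) and optionally `events.tsv`
#' (`onset_s`, `duration_s`, `trigger_unit`). Malformed rows raise an error
#' naming the file, line and field.
#'
#' @param spike_path Path to the spike table.
#' @param epoch_path Path to the epoch table.
#' @param event_path Optional path to the event table.
#' @param dead_time_s Dead time used to validate event spacing (default 20 ms).
#' @return A validated [session()] object.
#' @export
read_session <- function(spike_path, epoch_path, event_path = NULL,
                         dead_time_s = 0.020) {
  sp <- .read_table_checked(spike_path,
                            c("unit_id", "time_s", "cell_class", "shank"))
  time_s <- .parse_numeric_col(sp, "time_s", spike_path)
  shank <- .parse_numeric_col(sp, "shank", spike_path)
  bad_class <- which(!(sp$cell_class %in% .CELL_CLASSES))
  if (length(bad_class)) {
    stop(sprintf("file '%s', line %d, field 'cell_class': invalid value '%s'",
                 spike_path, bad_class[1L] + 1L, sp$cell_class[bad_class[1L]]))
  }
  uid <- factor(sp$unit_id, levels = unique(sp$unit_id))
  trains <- lapply(split(seq_along(time_s), uid), function(idx) {
    u <- as.character(sp$unit_id[idx[1L]])
    cls <- unique(sp$cell_class[idx])
    shk <- unique(shank[idx])
    if (length(cls) > 1L) stop("unit '", u, "' has inconsistent cell_class")
    if (length(shk) > 1L) stop("unit '", u, "' has inconsistent shank")
    spike_train(u, time_s[idx], cls, shk)
  })

  ep <- .read_table_checked(epoch_path, c("label", "start_s", "end_s"))
  epochs <- epoch_set(ep$label,
                      .parse_numeric_col(ep, "start_s", epoch_path),
                      .parse_numeric_col(ep, "end_s", epoch_path))

  events <- NULL
  if (!is.null(event_path)) {
    ev <- .read_table_checked(event_path,
                              c("onset_s", "duration_s", "trigger_unit"))
    if (nrow(ev)) {
      onset <- .parse_numeric_col(ev, "onset_s", event_path)
      dur <- unique(.parse_numeric_col(ev, "duration_s", event_path))
      if (length(dur) > 1L) stop("file '", event_path,
                                 "': events have mixed durations")
      trig <- ev$trigger_unit
      trig[!nzchar(trig)] <- NA_character_
      events <- stim_events(onset, duration_s = dur,
                            dead_time_s = dead_time_s, trigger_unit = trig)
    } else {
      events <- stim_events(numeric(0))
    }
  }
  session(trains, epochs, events)
}

#' Write a session to delimited-text files
#'
#' Writes `spikes.tsv`, `epochs.tsv` and `events.tsv` into `out_dir` with
#' times serialized at fixed 6-decimal precision (microseconds), so that
#' [read_session()] restores the session bit-identically when all times are
#' multiples of 1 microsecond.
#'
#' @param session A [session()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_session <- function(session, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c(spikes = file.path(out_dir, "spikes.tsv"),
             epochs = file.path(out_dir, "epochs.tsv"),
             events = file.path(out_dir, "events.tsv"))

  con <- file(paths["spikes"], "w")
  writeLines("unit_id\ttime_s\tcell_class\tshank", con)
  for (tr in session$trains) {
    if (!length(tr$times)) next
    writeLines(sprintf("%s\t%.6f\t%s\t%d", tr$unit_id, tr$times,
                       tr$cell_class, tr$shank), con)
  }
  close(con)

  con <- file(paths["epochs"], "w")
  writeLines("label\tstart_s\tend_s", con)
  writeLines(sprintf("%s\t%.6f\t%.6f", session$epochs$label,
                     session$epochs$start_s, session$epochs$end_s), con)
  close(con)

  ev <- session$events
  con <- file(paths["events"], "w")
  writeLines("onset_s\tduration_s\ttrigger_unit", con)
  if (length(ev$onsets)) {
    trig <- ifelse(is.na(ev$trigger_unit), "", ev$trigger_unit)
    writeLines(sprintf("%.6f\t%.6f\t%s", ev$onsets, ev$duration_s, trig), con)
  }
  close(con)
  invisible(paths)
}
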