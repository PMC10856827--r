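#' Detect gait-cycle boundaries from the anterior-posterior foot position
#'
#' Gait cycles are delimited by maxima of the right-foot anterior-posterior
#' position relative to the pelvis. A sample is a candidate boundary when it
#' is a local maximum whose height exceeds the signal minimum by
#' `prominence_frac` of the signal range; candidates closer than
#' `min_period_s` are resolved greedily in favour of the higher peak. The
#' default minimum period (0.4 s) lies below any plausible running stride
#' period.
#'
#' @param rec A `session_recording` containing a `foot_ap_position` channel.
#' @param min_period_s Minimum separation between boundaries (s).
#' @param prominence_frac Required height above the signal minimum, as a
#'   fraction of the signal range.
#' @return Object of class `cycle_boundaries`: sample `indices` of the
#'   detected maxima, derived stride `durations` (s), and the sample rate.
#' @export
detect_cycles <- function(rec, min_period_s = 0.4, prominence_frac = 0.1) {
  stopifnot(inherits(rec, "session_recording"))
  if (!AP_SIGNAL %in% colnames(rec$signals)) {
    stop("recording has no ", AP_SIGNAL, " channel")
  }
  x <- rec$signals[, AP_SIGNAL]
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to detect maxima")
  rng <- max(x) - min(x)
  if (rng == 0) {
    stop("segmentation failure: constant ", AP_SIGNAL,
         " signal (0 candidate maxima)")
  }
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L  # interior local maxima
  cand <- cand[x[cand] >= min(x) + prominence_frac * rng]
  # enforce minimum separation, keeping higher peaks first
  min_gap <- min_period_s * rec$sample_rate
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  idx <- sort(keep)
  if (length(idx) < 2) {
    stop(sprintf(paste0("segmentation failure: %d qualifying maxima ",
                        "(need >= 2); %d raw local maxima, range %.3g, ",
                        "min separation %.3g s"),
                 length(idx), length(cand), rng, min_period_s))
  }
  durations <- diff(idx) / rec$sample_rate
  structure(list(indices = idx, durations = durations,
                 sample_rate = rec$sample_rate,
                 plausible_band = c(0.4, 1.5)),
            class = "cycle_boundaries")
}

#' @export
print.cycle_boundaries <- function(x, ...) {
  cat(sprintf("Cycle boundaries: %d maxima, %d cycles, stride %.3f +/- %.3f s\n",
              length(x$indices), length(x$durations),
              mean(x$durations), sd(x$durations)))
  invisible(x)
}

#' Trim acceleration and deceleration cycles
#'
#' Removes the first and last `n_trim` complete cycles, discarding the
#' transient strides at the start and end of a run along the track.
#'
#' @param boundaries A `cycle_boundaries` object.
#' @param n_trim Cycles to drop from each end.
#' @return Trimmed `cycle_boundaries`.
#' @export
trim_transients <- function(boundaries, n_trim = 3L) {
  stopifnot(inherits(boundaries, "cycle_boundaries"), n_trim >= 0)
  n_cycles <- length(boundaries$indices) - 1L
  if (n_cycles - 2L * n_trim < 1L) {
    stop(sprintf("cannot trim %d cycles from each end of %d cycles",
                 n_trim, n_cycles))
  }
  if (n_trim == 0L) return(boundaries)
  idx <- boundaries$indices[(n_trim + 1L):(length(boundaries$indices) - n_trim)]
  boundaries$indices <- idx
  boundaries$durations <- diff(idx) / boundaries$sample_rate
  boundaries
}

#' Time-normalize gait cycles to 101 points and average
#'
#' Each boundary-to-boundary window of every angle channel is resampled by
#' linear interpolation onto 101 evenly spaced points (percent-of-cycle grid
#' 0, 1, ..., 100, inclusive of both boundary samples). Cycles whose duration
#' deviates more than 3 SD from the run median are dropped before averaging
#' (a guard against false maxima; logged via `message()`). The mean waveform
#' is the pointwise mean over retained cycles and stride frequency is the
#' reciprocal of the mean retained stride duration.
#'
#' @param rec A `session_recording`.
#' @param boundaries A `cycle_boundaries` object for `rec` (typically after
#'   [trim_transients()]).
#' @param signals Channels to normalize; defaults to all angle channels
#'   present.
#' @return Object of class `cycle_set`: per-signal `cycles` matrices
#'   (`n_cycles x 101`), the 101-row `mean` waveform matrix,
#'   `n_cycles_used`, `stride_frequency` (Hz), and the recording metadata.
#' @export
normalize_cycles <- function(rec, boundaries,
                             signals = intersect(GAIT_SIGNALS,
                                                 colnames(rec$signals))) {
  stopifnot(inherits(rec, "session_recording"),
            inherits(boundaries, "cycle_boundaries"))
  idx <- boundaries$indices
  if (length(idx) < 2) stop("need at least one retained cycle")
  if (any(diff(idx) < 2)) stop("cycle shorter than 2 samples")
  dur <- diff(idx) / rec$sample_rate
  drop <- rep(FALSE, length(dur))
  if (length(dur) >= 3) {
    s <- sd(dur)
    # the 2-sample floor keeps boundary quantization (durations alternating
    # by one sample) from masquerading as duration outliers
    if (s > 0) {
      drop <- abs(dur - median(dur)) > pmax(3 * s, 2 / rec$sample_rate)
    }
  }
  if (any(drop)) {
    message(sprintf("dropping %d cycle(s) with outlying duration", sum(drop)))
  }
  starts <- idx[-length(idx)][!drop]
  ends <- idx[-1L][!drop]
  n_cycles <- length(starts)
  if (n_cycles < 1) stop("no cycles left after duration screening")

  grid <- seq(0, 1, length.out = 101L)
  t_start <- rec$time[starts]
  t_end <- rec$time[ends]
  # all target times at once: one interpolation pass per signal
  target <- rep(t_start, each = 101L) +
    rep(t_end - t_start, each = 101L) * rep(grid, times = n_cycles)
  cycles <- lapply(signals, function(sg) {
    y <- approx(rec$time, rec$signals[, sg], xout = target)$y
    matrix(y, nrow = n_cycles, ncol = 101L, byrow = TRUE)
  })
  names(cycles) <- signals
  mean_wave <- vapply(cycles, colMeans, numeric(101L))

  structure(list(cycles = cycles, mean = mean_wave,
                 n_cycles_used = n_cycles,
                 n_cycles_dropped = sum(drop),
                 stride_frequency = 1 / mean((t_end - t_start)),
                 participant = rec$participant, day = rec$day,
                 surface = rec$surface, run = rec$run,
                 calibration = rec$calibration,
                 avg_speed = rec$avg_speed),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf(
    "Normalized cycle set: %d cycles x 101 points, %d signal(s), SF %.3f Hz\n",
    x$n_cycles_used, length(x$cycles), x$stride_frequency))
  invisible(x)
}

#' Segment one recording end to end
#'
#' Convenience wrapper: [detect_cycles()], [trim_transients()],
#' [normalize_cycles()].
#'
#' @param rec A `session_recording`.
#' @param n_trim Cycles trimmed from each end.
#' @param min_period_s,prominence_frac Passed to [detect_cycles()].
#' @return A `cycle_set`.
#' @export
segment_recording <- function(rec, n_trim = 3L, min_period_s = 0.4,
                              prominence_frac = 0.1) {
  b <- detect_cycles(rec, min_period_s = min_period_s,
                     prominence_frac = prominence_frac)
  b <- trim_transients(b, n_trim = n_trim)
  normalize_cycles(rec, b)
}

#' Write a normalized cycle set to CSV
#'
#' 101 rows (percent of cycle 0-100), one column per signal's mean waveform.
#'
#' @param cycle_set A `cycle_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cycle_set <- function(cycle_set, path) {
  stopifnot(inherits(cycle_set, "cycle_set"))
  dt <- data.table::data.table(percent = 0:100)
  for (nm in colnames(cycle_set$mean)) dt[[nm]] <- cycle_set$mean[, nm]
  data.table::fwrite(dt, path)
  invisible(path)
}
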