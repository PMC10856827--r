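#' Discrete joint-angle variable specifications
#'
#' The nine discrete variables read from the averaged 101-point waveforms.
#' Initial variables are the waveform value at 0% of the gait cycle; peak
#' variables are the signed extremum over the approximated stance phase,
#' the closed grid interval 0-40% (41 samples). Extremum directions follow
#' the sign conventions of ISB-based inertial motion capture: adduction is
#' negative (peak hip adduction is a minimum), knee flexion and ankle
#' dorsiflexion are positive maxima, and eversion is positive (initial
#' inversion shows as a negative value of the same channel).
#'
#' @return `data.frame` with columns `name`, `signal`, `kind`
#'   (`initial`/`peak`), `window_lo`, `window_hi` (percent of cycle), and
#'   `direction` (`max`/`min`).
#' @export
variable_specs <- function() {
  data.frame(
    name = ANGLE_VARIABLES,
    signal = c("hip_flexion", "hip_abduction", "hip_abduction",
               "knee_flexion", "knee_flexion",
               "ankle_dorsiflexion", "ankle_dorsiflexion",
               "ankle_eversion", "ankle_eversion"),
    kind = c("initial", "initial", "peak", "initial", "peak",
             "initial", "peak", "initial", "peak"),
    window_lo = 0L,
    window_hi = 40L,
    direction = c(NA, NA, "min", NA, "max", NA, "max", NA, "max"),
    stringsAsFactors = FALSE
  )
}

#' Extract discrete features from an averaged waveform set
#'
#' Reads the nine discrete joint-angle variables off the averaged waveform of
#' a [normalize_cycles()] result, and appends running speed (`RS`, the
#' timing-gate value carried by the recording) and stride frequency (`SF`).
#'
#' @param cycle_set A `cycle_set`.
#' @param specs Variable specifications, see [variable_specs()].
#' @param avg_speed Override for the running speed (m/s); defaults to the
#'   value stored in the cycle set.
#' @return One-row `data.frame`: keys, the nine angle variables (deg), `RS`
#'   (m/s), `SF` (Hz).
#' @export
extract_features <- function(cycle_set, specs = variable_specs(),
                             avg_speed = cycle_set$avg_speed) {
  stopifnot(inherits(cycle_set, "cycle_set"))
  wave <- cycle_set$mean
  row <- data.frame(participant = cycle_set$participant,
                    day = cycle_set$day, surface = cycle_set$surface,
                    run = cycle_set$run, calibration = cycle_set$calibration)
  for (i in seq_len(nrow(specs))) {
    sg <- specs$signal[i]
    if (!sg %in% colnames(wave)) {
      stop("missing signal in averaged waveform: ", sg)
    }
    w <- wave[, sg]
    if (specs$kind[i] == "initial") {
      val <- w[1L]
    } else {
      lo <- specs$window_lo[i]; hi <- specs$window_hi[i]
      if (lo < 0 || hi > 100 || lo > hi) {
        stop("peak window outside the 0-100 grid for ", specs$name[i])
      }
      win <- w[(lo + 1L):(hi + 1L)]
      val <- if (specs$direction[i] == "max") max(win) else min(win)
    }
    row[[specs$name[i]]] <- val
  }
  row$RS <- avg_speed
  row$SF <- cycle_set$stride_frequency
  row
}

#' Build a feature table from a cohort of cycle sets
#'
#' One row per (participant, day, surface, run, calibration).
#'
#' @param cycle_sets List of `cycle_set` objects.
#' @param specs Variable specifications.
#' @return Feature table `data.frame`.
#' @export
build_feature_table <- function(cycle_sets, specs = variable_specs()) {
  rows <- lapply(cycle_sets, function(cs) {
    tryCatch(extract_features(cs, specs = specs),
             error = function(e) {
               stop(sprintf(
                 "feature extraction failed for participant %s day %d %s run %d calibration %d: %s",
                 cs$participant, cs$day, cs$surface, cs$run, cs$calibration,
                 conditionMessage(e)), call. = FALSE)
             })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
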