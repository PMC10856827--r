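#' Construct a session recording
#'
#' One continuous run's multichannel time series with identifying metadata.
#' Joint-angle channels are in degrees; the right-foot anterior-posterior
#' position is in metres relative to the pelvis.
#'
#' @param participant Participant identifier.
#' @param day Testing day (1-based).
#' @param surface Surface label.
#' @param run Run index within the day (1-based study label).
#' @param calibration Calibration index (1-based).
#' @param sample_rate Sampling rate in Hz.
#' @param time Time vector in seconds; strictly increasing, uniform.
#' @param signals Numeric matrix, one named column per channel, one row per
#'   sample.
#' @param avg_speed Timing-gate average running speed (m/s); `NA` if unknown.
#' @return Object of class `session_recording`.
#' @export
session_recording <- function(participant, day, surface, run, calibration,
                              sample_rate, time, signals,
                              avg_speed = NA_real_) {
  signals <- as.matrix(signals)
  if (is.null(colnames(signals))) stop("signals must have column names")
  if (length(time) != nrow(signals)) {
    stop("time and signals must have equal length")
  }
  if (length(time) < 2) stop("a recording needs at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * mean(dt) + 1e-12) {
    stop("time must be uniformly sampled")
  }
  if (abs(mean(dt) - 1 / sample_rate) > 1e-6 / sample_rate) {
    stop("sample_rate inconsistent with time step")
  }
  structure(list(participant = participant, day = as.integer(day),
                 surface = as.character(surface), run = as.integer(run),
                 calibration = as.integer(calibration),
                 sample_rate = sample_rate, time = as.numeric(time),
                 signals = signals, avg_speed = as.numeric(avg_speed)),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "Session recording: participant %s, day %d, %s, run %d, calibration %d\n",
    x$participant, x$day, x$surface, x$run, x$calibration))
  cat(sprintf("  %d samples at %g Hz (%.1f s), channels: %s\n",
              length(x$time), x$sample_rate,
              length(x$time) / x$sample_rate,
              paste(colnames(x$signals), collapse = ", ")))
  if (!is.na(x$avg_speed)) cat(sprintf("  avg speed %.2f m/s\n", x$avg_speed))
  invisible(x)
}

SESSION_META_COLS <- c("participant_id", "day", "surface", "run",
                       "calibration", "time_s")

#' Write a session recording to CSV
#'
#' Long form, one row per sample: `participant_id, day, surface, run,
#' calibration, time_s`, then one column per signal.
#'
#' @param rec A `session_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_session <- function(rec, path) {
  stopifnot(inherits(rec, "session_recording"))
  dt <- data.table::data.table(participant_id = rec$participant,
                               day = rec$day, surface = rec$surface,
                               run = rec$run, calibration = rec$calibration,
                               time_s = rec$time)
  for (nm in colnames(rec$signals)) dt[[nm]] <- rec$signals[, nm]
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a session recording from CSV
#'
#' @param path CSV path in the schema written by [write_session()].
#' @param avg_speed Timing-gate speed (m/s), normally supplied from the
#'   cohort manifest.
#' @param required_signals Signal columns that must be present; defaults to
#'   the channels needed by the downstream pipeline.
#' @return A `session_recording`.
#' @export
read_session <- function(path, avg_speed = NA_real_,
                         required_signals = c(GAIT_SIGNALS, AP_SIGNAL)) {
  dt <- data.table::fread(path)
  missing_meta <- setdiff(SESSION_META_COLS, names(dt))
  if (length(missing_meta)) {
    stop("session file missing required column(s): ",
         paste(missing_meta, collapse = ", "))
  }
  signal_cols <- setdiff(names(dt), SESSION_META_COLS)
  missing_sig <- setdiff(required_signals, signal_cols)
  if (length(missing_sig)) {
    stop("session file missing required column(s): ",
         paste(missing_sig, collapse = ", "))
  }
  for (col in c("participant_id", "day", "surface", "run", "calibration")) {
    if (length(unique(dt[[col]])) != 1L) {
      stop("mixed values in metadata column: ", col)
    }
  }
  time <- dt$time_s
  if (any(diff(time) <= 0)) stop("non-monotone time in ", path)
  steps <- diff(time)
  if (max(steps) - min(steps) > 1e-6 * mean(steps)) {
    stop("mixed sample rates in ", path)
  }
  fs <- 1 / mean(steps)
  signals <- as.matrix(dt[, signal_cols, with = FALSE])
  colnames(signals) <- signal_cols
  session_recording(participant = dt$participant_id[1L], day = dt$day[1L],
                    surface = dt$surface[1L], run = dt$run[1L],
                    calibration = dt$calibration[1L],
                    sample_rate = fs, time = time, signals = signals,
                    avg_speed = avg_speed)
}

#' Write a cohort of recordings plus manifest (and optional truth sidecar)
#'
#' Writes one session CSV per recording, a `manifest.csv` with columns
#' `participant_id, day, surface, run, calibration, file, avg_speed_mps`,
#' and, when simulation truth is supplied, a `truth.json` sidecar holding the
#' variance components, template base features, true ICC table, and true
#' cycle boundaries.
#'
#' @param recordings List of `session_recording` objects.
#' @param dir Output directory (created if needed).
#' @param truth Optional `simulation_truth` object.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(recordings, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(recordings, function(rec) {
    file <- sprintf("session_p%s_d%d_%s_r%d_c%d.csv",
                    rec$participant, rec$day, rec$surface, rec$run,
                    rec$calibration)
    write_session(rec, file.path(dir, file))
    data.table::data.table(participant_id = rec$participant, day = rec$day,
                           surface = rec$surface, run = rec$run,
                           calibration = rec$calibration, file = file,
                           avg_speed_mps = rec$avg_speed)
  })
  manifest <- data.table::rbindlist(rows)
  mpath <- file.path(dir, "manifest.csv")
  data.table::fwrite(manifest, mpath)
  if (!is.null(truth)) write_truth(truth, file.path(dir, "truth.json"))
  invisible(mpath)
}

#' Read a cohort via its manifest
#'
#' @param dir Directory containing `manifest.csv` and the session files.
#' @return List of `session_recording` objects with manifest speeds attached.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  manifest <- data.table::fread(mpath)
  lapply(seq_len(nrow(manifest)), function(i) {
    read_session(file.path(dir, manifest$file[i]),
                 avg_speed = manifest$avg_speed_mps[i])
  })
}

#' Serialize simulation truth to JSON
#'
#' @param truth A `simulation_truth` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  cfg <- truth$config
  icc <- expand.grid(variable = ANGLE_VARIABLES,
                     comparison = c("between_day", "within_day",
                                    "calibration"),
                     stringsAsFactors = FALSE)
  icc$true_icc <- mapply(function(v, ct) truth_icc(truth, v, ct),
                         icc$variable, icc$comparison)
  payload <- list(
    design = list(n_participants = cfg$n_participants, n_days = cfg$n_days,
                  surfaces = cfg$surfaces, runs = cfg$runs,
                  n_calibrations = cfg$n_calibrations,
                  strides_per_run = cfg$strides_per_run,
                  n_trim = cfg$n_trim, sample_rate = cfg$sample_rate,
                  seed = cfg$seed),
    variance_components = as.data.frame(cfg$variance_components),
    base_features = as.list(truth$base_features),
    n_strides_averaged = truth$n_strides_averaged,
    true_icc = icc,
    boundaries = truth$boundaries)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Validate the structural completeness of a cohort
#'
#' Pure report: checks that the full crossing of the observed participant,
#' day, surface, run, and calibration levels is present, that no key occurs
#' twice, and that all recordings share one sample rate. Never mutates data.
#'
#' @param recordings List of `session_recording` objects.
#' @return `data.frame` of issues with columns `issue` and `detail`
#'   (zero rows when the cohort is complete and consistent).
#' @export
validate_cohort <- function(recordings) {
  issues <- list()
  keys <- vapply(recordings, function(r) {
    paste(r$participant, r$day, r$surface, r$run, r$calibration, sep = "|")
  }, character(1))
  dup <- unique(keys[duplicated(keys)])
  for (k in dup) {
    issues[[length(issues) + 1L]] <-
      data.frame(issue = "duplicate_key", detail = k)
  }
  levels_of <- function(f) sort(unique(vapply(recordings, f, f(recordings[[1L]]))))
  expected <- expand.grid(
    participant = levels_of(function(r) as.character(r$participant)),
    day = levels_of(function(r) r$day),
    surface = levels_of(function(r) r$surface),
    run = levels_of(function(r) r$run),
    calibration = levels_of(function(r) r$calibration),
    stringsAsFactors = FALSE)
  expected_keys <- paste(expected$participant, expected$day, expected$surface,
                         expected$run, expected$calibration, sep = "|")
  for (k in setdiff(expected_keys, keys)) {
    issues[[length(issues) + 1L]] <-
      data.frame(issue = "missing_cell", detail = k)
  }
  rates <- vapply(recordings, function(r) r$sample_rate, numeric(1))
  if (length(unique(round(rates, 6))) > 1L) {
    issues[[length(issues) + 1L]] <-
      data.frame(issue = "sample_rate_mismatch",
                 detail = paste(sort(unique(round(rates, 6))),
                                collapse = ", "))
  }
  if (!length(issues)) {
    return(data.frame(issue = character(), detail = character()))
  }
  do.call(rbind, issues)
}

#' Write / read a feature table CSV
#'
#' Columns exactly: `participant, day, surface, run, calibration, IHF, IHA,
#' PHA, IKF, PKF, IAD, PAD, IAI, PAE, RS, SF`.
#'
#' @param features A feature table `data.frame`.
#' @param path CSV path.
#' @return `path` (write) or the feature table (read).
#' @export
write_feature_table <- function(features, path) {
  cols <- c(KEY_COLUMNS, ANGLE_VARIABLES, "RS", "SF")
  missing <- setdiff(cols, names(features))
  if (length(missing)) {
    stop("feature table missing column(s): ", paste(missing, collapse = ", "))
  }
  data.table::fwrite(features[, cols], path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  dt <- data.table::fread(path)
  cols <- c(KEY_COLUMNS, ANGLE_VARIABLES, "RS", "SF")
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stop("feature table missing column(s): ", paste(missing, collapse = ", "))
  }
  as.data.frame(dt)
}

#' Placeholder for proprietary motion-capture exports
#'
#' Parsing of the vendor MVNX export is out of scope. This stub documents the
#' expected mapping: sensor-fusion joint angles (ZXY Euler sequences per the
#' ISB recommendation) for the right hip, knee, and ankle map onto the
#' channels `hip_flexion`, `hip_abduction`, `knee_flexion`,
#' `ankle_dorsiflexion`, `ankle_eversion` (deg), and the right-foot segment
#' position in the pelvis-fixed frame's anterior axis maps onto
#' `foot_ap_position` (m). Convert such an export to the session CSV schema
#' with external tooling, then load it with [read_session()].
#'
#' @param path Path to an MVNX export.
#' @export
convert_mvnx <- function(path) {
  stop("MVNX parsing is not implemented; convert '", path,
       "' to the session CSV schema (see ?convert_mvnx) and use ",
       "read_session()")
}
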