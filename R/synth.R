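#' Default joint-angle template waveforms
#'
#' Each template is a low-order Fourier series over percent of gait cycle
#' (period 100), so waveforms are continuous across stride boundaries. The
#' coefficient vector is `c(a0, a1, b1, a2, b2, ...)` for
#' `a0 + sum_j a_j cos(2*pi*j*p/100) + b_j sin(2*pi*j*p/100)`.
#' Shapes are plausible for recreational over-ground running: initial values
#' and stance-phase extrema fall in the ranges typically reported for hip,
#' knee, and ankle angles (e.g. initial knee flexion near 7.5 deg, peak knee
#' flexion in stance near 43 deg). The exact shape does not enter the
#' reliability mathematics; level offsets shift whole waveforms.
#'
#' @return Named list of numeric coefficient vectors, one per angle signal.
#' @export
default_templates <- function() {
  list(
    hip_flexion = c(21.495, 15.318, -7.919, -1.413, -0.094, -0.429, 0.016,
                    -0.173, -0.007, 0.007, 0.007),
    hip_abduction = c(-0.745, -1.633, -5.895, 2.042, -0.507, 0.264, 0.326,
                      -0.035, 0.077, -0.054, 0.008),
    knee_flexion = c(36.847, -6.632, -15.098, -20.637, 7.82, -1.119, 0.652,
                     -0.362, -0.612, -0.404, 0.119),
    ankle_dorsiflexion = c(4.459, 9.78, 7.231, -9.617, 1.15, 2.754, -1.297,
                           -0.604, 0.539, -0.012, -0.261),
    ankle_eversion = c(-0.435, -3.124, 8.994, -3.33, 1.335, -0.408, 0.109,
                       -0.046, 0.041, -0.085, 0.012)
  )
}

#' Evaluate a Fourier template at percent-of-cycle positions
#'
#' @param coefs Coefficient vector `c(a0, a1, b1, a2, b2, ...)`.
#' @param p Percent-of-cycle positions (numeric; period 100).
#' @return Numeric vector of template values (deg).
#' @export
eval_template <- function(coefs, p) {
  stopifnot(is.numeric(coefs), length(coefs) %% 2 == 1)
  nh <- (length(coefs) - 1L) / 2L
  y <- rep(coefs[1L], length(p))
  w <- 2 * pi * p / 100
  for (j in seq_len(nh)) {
    y <- y + coefs[2L * j] * cos(j * w) + coefs[2L * j + 1L] * sin(j * w)
  }
  y
}

#' Default per-signal variance components
#'
#' Variance components (deg^2) of the hierarchical offset model, per angle
#' signal: `runner` (stable between-runner differences), `day` (day-to-day
#' drift in movement pattern and sensor placement), `run` (run-to-run
#' variation within a day), `calibration` (sensor-to-segment calibration
#' error), and `stride` (stride-to-stride variability, averaged out over the
#' retained strides of a run). Defaults put roughly half of the between-day
#' error at the day level and split the rest between run and calibration
#' levels, giving a true between-day ICC near 0.8 and within-day ICC near
#' 0.95 for every signal when ~40 strides are averaged.
#'
#' @return Matrix with one row per angle signal and columns
#'   `runner`, `day`, `run`, `calibration`, `stride`.
#' @export
default_variance_components <- function() {
  comp <- c(runner = 4, day = 0.55, run = 0.25, calibration = 0.2,
            stride = 0.4)
  out <- matrix(rep(comp, each = length(GAIT_SIGNALS)),
                nrow = length(GAIT_SIGNALS),
                dimnames = list(GAIT_SIGNALS, names(comp)))
  out
}

#' Build a simulation configuration
#'
#' Defines the study conditions emulated by the synthetic cohort generator:
#' a five-day repeated-measures design with two surfaces, two analyzed runs
#' per surface and day (labelled 1 and 3, the first and third run of the
#' session), and two calibration copies of every run. Defaults reproduce the
#' canonical design: 17 runners x 5 days x 2 surfaces x 2 runs x
#' 2 calibrations, 46 strides per run (40 retained after trimming 3
#' acceleration and 3 deceleration cycles), sampled at 240 Hz.
#'
#' @param n_participants Number of runners.
#' @param n_days Number of testing days.
#' @param surfaces Character vector of surface labels.
#' @param runs Integer labels of the analyzed runs within a day (first
#'   element is used for between-day and calibration comparisons).
#' @param n_calibrations Calibration copies per run (>= 1).
#' @param strides_per_run Gait cycles per recording (>= 3).
#' @param n_trim Cycles trimmed from each end before averaging.
#' @param sample_rate Sampling rate in Hz.
#' @param variance_components Per-signal variance matrix as returned by
#'   [default_variance_components()]; all entries in deg^2.
#' @param templates Named list of Fourier templates (see
#'   [default_templates()]).
#' @param speed_mean,speed_sd Mean and between-runner SD of running speed
#'   (m/s).
#' @param speed_run_sd Within-runner run-to-run SD of true speed (m/s).
#' @param gate_sd SD of timing-gate measurement noise on speed (m/s).
#' @param stride_freq_mean,stride_freq_sd Mean and between-runner SD of
#'   stride frequency (Hz).
#' @param period_jitter_frac Per-stride period jitter as a fraction of the
#'   runner's stride period (0 disables jitter; 0.01 exercises segmentation
#'   robustness).
#' @param ap_amplitude Amplitude of the anterior-posterior foot-position
#'   oscillation (m).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 17L,
                       n_days = 5L,
                       surfaces = c("asphalt", "woodchip"),
                       runs = c(1L, 3L),
                       n_calibrations = 2L,
                       strides_per_run = 46L,
                       n_trim = 3L,
                       sample_rate = 240,
                       variance_components = default_variance_components(),
                       templates = default_templates(),
                       speed_mean = 3.4, speed_sd = 0.3,
                       speed_run_sd = 0.1, gate_sd = 0.05,
                       stride_freq_mean = 1.40, stride_freq_sd = 0.05,
                       period_jitter_frac = 0,
                       ap_amplitude = 0.5,
                       seed = 1L) {
  stopifnot(n_participants >= 1, n_days >= 1, length(surfaces) >= 1,
            length(runs) >= 1, n_calibrations >= 1,
            sample_rate > 0, n_trim >= 0,
            speed_sd >= 0, speed_run_sd >= 0, gate_sd >= 0,
            stride_freq_mean > 0, stride_freq_sd >= 0,
            period_jitter_frac >= 0, ap_amplitude > 0)
  if (strides_per_run < 3) {
    stop("strides_per_run must be >= 3 (cannot trim and average)")
  }
  if (anyDuplicated(runs)) stop("run labels must be unique")
  vc <- as.matrix(variance_components)
  if (!all(GAIT_SIGNALS %in% rownames(vc))) {
    stop("variance_components must have one row per signal: ",
         paste(GAIT_SIGNALS, collapse = ", "))
  }
  needed <- c("runner", "day", "run", "calibration", "stride")
  if (!all(needed %in% colnames(vc))) {
    stop("variance_components must have columns: ",
         paste(needed, collapse = ", "))
  }
  if (any(vc < 0)) stop("all variance components must be >= 0")
  if (!all(GAIT_SIGNALS %in% names(templates))) {
    stop("templates must cover all signals")
  }
  cfg <- list(n_participants = as.integer(n_participants),
              n_days = as.integer(n_days),
              surfaces = as.character(surfaces),
              runs = as.integer(runs),
              n_calibrations = as.integer(n_calibrations),
              strides_per_run = as.integer(strides_per_run),
              n_trim = as.integer(n_trim),
              sample_rate = sample_rate,
              variance_components = vc[GAIT_SIGNALS, needed, drop = FALSE],
              templates = templates,
              speed_mean = speed_mean, speed_sd = speed_sd,
              speed_run_sd = speed_run_sd, gate_sd = gate_sd,
              stride_freq_mean = stride_freq_mean,
              stride_freq_sd = stride_freq_sd,
              period_jitter_frac = period_jitter_frac,
              ap_amplitude = ap_amplitude,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration:\n")
  cat(sprintf("  %d participants x %d days x %d surfaces x %d runs x %d calibrations\n",
              x$n_participants, x$n_days, length(x$surfaces),
              length(x$runs), x$n_calibrations))
  cat(sprintf("  %d strides/run (trim %d each end), %g Hz, seed %d\n",
              x$strides_per_run, x$n_trim, x$sample_rate, x$seed))
  invisible(x)
}

# Template feature values on the 101-point grid: what feature extraction
# returns for a zero-offset waveform evaluated exactly on the grid.
template_base_features <- function(templates, specs = variable_specs()) {
  grid <- 0:100
  vals <- vapply(seq_len(nrow(specs)), function(i) {
    w <- eval_template(templates[[specs$signal[i]]], grid)
    if (specs$kind[i] == "initial") {
      w[1L]
    } else {
      win <- w[(specs$window_lo[i] + 1L):(specs$window_hi[i] + 1L)]
      if (specs$direction[i] == "max") max(win) else min(win)
    }
  }, numeric(1))
  setNames(vals, specs$name)
}

# Draw the full set of hierarchical level effects for a configuration.
# All draws come from one seeded generator in a fixed, documented order:
# runner-level first, then day-, calibration-, run-, and stride-level,
# each looped participant-major.
draw_level_effects <- function(config) {
  np <- config$n_participants; nd <- config$n_days
  ns <- length(config$surfaces); nr <- length(config$runs)
  nc <- config$n_calibrations; nst <- config$strides_per_run
  nsig <- length(GAIT_SIGNALS)
  vc <- config$variance_components

  set.seed(config$seed)
  # runner level
  stride_freq <- rnorm(np, config$stride_freq_mean, config$stride_freq_sd)
  stride_freq <- pmax(stride_freq, 0.5)  # keep periods physical
  speed <- rnorm(np, config$speed_mean, config$speed_sd)
  runner_off <- matrix(rnorm(np * nsig, 0, rep(sqrt(vc[, "runner"]), each = np)),
                       np, nsig, dimnames = list(NULL, GAIT_SIGNALS))
  # day level: per (participant, day, surface)
  day_off <- array(rnorm(np * nd * ns * nsig, 0,
                         rep(sqrt(vc[, "day"]), each = np * nd * ns)),
                   dim = c(np, nd, ns, nsig),
                   dimnames = list(NULL, NULL, config$surfaces, GAIT_SIGNALS))
  # calibration level: per (participant, day, calibration); the same two
  # calibration trials of a day are applied to every run on both surfaces
  cal_off <- array(rnorm(np * nd * nc * nsig, 0,
                         rep(sqrt(vc[, "calibration"]), each = np * nd * nc)),
                   dim = c(np, nd, nc, nsig),
                   dimnames = list(NULL, NULL, NULL, GAIT_SIGNALS))
  # run level: per (participant, day, surface, run)
  run_off <- array(rnorm(np * nd * ns * nr * nsig, 0,
                         rep(sqrt(vc[, "run"]), each = np * nd * ns * nr)),
                   dim = c(np, nd, ns, nr, nsig),
                   dimnames = list(NULL, NULL, config$surfaces, NULL,
                                   GAIT_SIGNALS))
  # per-run true speed and gate noise
  speed_run <- array(rnorm(np * nd * ns * nr, 0, config$speed_run_sd),
                     dim = c(np, nd, ns, nr))
  gate_noise <- array(rnorm(np * nd * ns * nr, 0, config$gate_sd),
                      dim = c(np, nd, ns, nr))
  # stride level: offsets per stride, shared by the calibration copies
  stride_off <- array(rnorm(np * nd * ns * nr * nst * nsig, 0,
                            rep(sqrt(vc[, "stride"]),
                                each = np * nd * ns * nr * nst)),
                      dim = c(np, nd, ns, nr, nst, nsig))
  # per-stride period jitter (multiplicative)
  jitter <- array(rnorm(np * nd * ns * nr * nst, 0, config$period_jitter_frac),
                  dim = c(np, nd, ns, nr, nst))

  list(stride_freq = stride_freq, speed = speed, runner_off = runner_off,
       day_off = day_off, cal_off = cal_off, run_off = run_off,
       speed_run = speed_run, gate_noise = gate_noise,
       stride_off = stride_off, jitter = jitter)
}

#' Generate a synthetic cohort of session recordings
#'
#' Simulates one continuous recording per participant x day x surface x run
#' x calibration. Each angle channel is a periodic template waveform repeated
#' at the runner's stride period with additive level offsets drawn once per
#' runner, day, run, calibration, and stride. The right-foot
#' anterior-posterior position channel is a cosine whose maxima fall exactly
#' on the true cycle boundaries. The two calibration copies of a run share
#' all stride-level data and differ only by the calibration offset.
#'
#' @param config A [sim_config()] object.
#' @return List with elements `recordings` (list of `session_recording`) and
#'   `truth` (a `simulation_truth` object holding realized level effects,
#'   true cycle boundaries, template base features, and the configuration).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  eff <- draw_level_effects(config)
  np <- config$n_participants; nd <- config$n_days
  surfaces <- config$surfaces; runs <- config$runs
  nc <- config$n_calibrations; nst <- config$strides_per_run
  fs <- config$sample_rate

  recordings <- vector("list",
                       np * nd * length(surfaces) * length(runs) * nc)
  boundaries <- list()
  idx <- 0L
  for (p in seq_len(np)) {
    period <- 1 / eff$stride_freq[p]
    for (d in seq_len(nd)) {
      for (si in seq_along(surfaces)) {
        for (ri in seq_along(runs)) {
          per_stride <- period * (1 + eff$jitter[p, d, si, ri, ])
          per_stride <- pmax(per_stride, 0.25 * period)
          lead <- 0.6 * period
          b <- lead + c(0, cumsum(per_stride))   # nst + 1 boundary times (s)
          dur <- b[length(b)] + 0.6 * period
          n <- floor(dur * fs) + 1L
          t <- (0:(n - 1L)) / fs
          # stride index (0 = lead-in, nst + 1 = tail) and phase in [0, 1)
          k <- findInterval(t, b)
          b_ext <- c(b[1L] - period, b, b[length(b)] + period)
          lo <- b_ext[k + 1L]
          hi <- b_ext[k + 2L]
          phase <- (t - lo) / (hi - lo)
          # stride offsets for lead-in/tail reuse first/last stride (trimmed
          # downstream anyway)
          k_str <- pmin(pmax(k, 1L), nst)
          base_speed <- eff$speed[p] + eff$speed_run[p, d, si, ri]
          avg_speed <- base_speed + eff$gate_noise[p, d, si, ri]

          pgrid <- 100 * phase
          ang <- matrix(0, n, length(GAIT_SIGNALS),
                        dimnames = list(NULL, GAIT_SIGNALS))
          for (sg in seq_along(GAIT_SIGNALS)) {
            sig <- GAIT_SIGNALS[sg]
            w <- eval_template(config$templates[[sig]], pgrid)
            w <- w + eff$runner_off[p, sg] + eff$day_off[p, d, si, sg] +
              eff$run_off[p, d, si, ri, sg] +
              eff$stride_off[p, d, si, ri, , sg][k_str]
            ang[, sg] <- w
          }
          ap <- config$ap_amplitude * cos(2 * pi * phase)

          key <- sprintf("p%02d_d%d_%s_r%d", p, d, surfaces[si], runs[ri])
          boundaries[[key]] <- b
          for (cc in seq_len(nc)) {
            cal_mat <- matrix(eff$cal_off[p, d, cc, ], n,
                              length(GAIT_SIGNALS), byrow = TRUE)
            sig_mat <- cbind(ang + cal_mat, foot_ap_position = ap)
            idx <- idx + 1L
            recordings[[idx]] <- session_recording(
              participant = p, day = d, surface = surfaces[si],
              run = runs[ri], calibration = cc,
              sample_rate = fs, time = t, signals = sig_mat,
              avg_speed = avg_speed)
          }
        }
      }
    }
  }

  truth <- structure(
    list(config = config,
         effects = eff,
         boundaries = boundaries,
         base_features = template_base_features(config$templates),
         n_strides_averaged = config$strides_per_run - 2L * config$n_trim),
    class = "simulation_truth")
  list(recordings = recordings, truth = truth)
}

# Map a discrete variable name to its source signal.
variable_signal <- function(variable) {
  specs <- variable_specs()
  i <- match(variable, specs$name)
  if (is.na(i)) stop("unknown variable: ", variable)
  specs$signal[i]
}

#' Analytic ground-truth ICC of a simulated cohort
#'
#' Under the additive offset model, the two measurements of a comparison pair
#' share some variance components (which act as the between-subject variance
#' of the pair's two-column matrix) and differ in others (the error
#' variance). The true ICC is `shared / (shared + differing)`, where
#' stride-level variance enters divided by the number of averaged strides:
#' * between-day: shared = runner; differing = day + run + calibration +
#'   stride/m
#' * within-day (same day and calibration, two runs): shared = runner + day +
#'   calibration; differing = run + stride/m
#' * calibration (same run, two calibration copies): shared = runner + day +
#'   run + stride/m; differing = calibration
#'
#' @param truth A `simulation_truth` object (or a `sim_config`, in which case
#'   the number of averaged strides is derived from it).
#' @param variable Discrete variable name (one of `r
#'   paste(ANGLE_VARIABLES, collapse = ", ")`).
#' @param comparison_type One of `"between_day"`, `"within_day"`,
#'   `"calibration"`.
#' @return True ICC in `[0, 1]`.
#' @export
truth_icc <- function(truth, variable, comparison_type) {
  if (inherits(truth, "sim_config")) {
    config <- truth
    m <- max(config$strides_per_run - 2L * config$n_trim, 1L)
  } else {
    stopifnot(inherits(truth, "simulation_truth"))
    config <- truth$config
    m <- max(truth$n_strides_averaged, 1L)
  }
  comparison_type <- match.arg(comparison_type,
                               c("between_day", "within_day", "calibration"))
  sig <- variable_signal(variable)
  v <- config$variance_components[sig, ]
  stride_avg <- v[["stride"]] / m
  shared <- switch(comparison_type,
    between_day = v[["runner"]],
    within_day = v[["runner"]] + v[["day"]] + v[["calibration"]],
    calibration = v[["runner"]] + v[["day"]] + v[["run"]] + stride_avg)
  differing <- switch(comparison_type,
    between_day = v[["day"]] + v[["run"]] + v[["calibration"]] + stride_avg,
    within_day = v[["run"]] + stride_avg,
    calibration = v[["calibration"]])
  if (shared + differing == 0) return(NA_real_)
  unname(shared / (shared + differing))
}

#' True cycle boundary times of a simulated recording
#'
#' @param truth A `simulation_truth` object.
#' @param participant,day,surface,run Identifiers of the recording (the
#'   calibration copies share boundaries).
#' @return Numeric vector of boundary times in seconds.
#' @export
truth_boundaries <- function(truth, participant, day, surface, run) {
  stopifnot(inherits(truth, "simulation_truth"))
  key <- sprintf("p%02d_d%d_%s_r%d", participant, day, surface, run)
  b <- truth$boundaries[[key]]
  if (is.null(b)) stop("no such recording in truth: ", key)
  b
}

#' Simulate a feature table directly from the offset model
#'
#' Bypasses waveform synthesis and segmentation: every discrete feature is
#' its template base value plus the sum of the realized level offsets, with
#' the stride-level contribution averaged over the retained strides. This is
#' exactly the value the full pipeline extracts from noise-free waveforms, so
#' it supports fast large-scale estimator validation (e.g. ICC parameter
#' recovery across hundreds of cohorts).
#'
#' @param config A [sim_config()] object.
#' @return A feature table `data.frame` (see [build_feature_table()]).
#' @export
simulate_feature_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  eff <- draw_level_effects(config)
  base <- template_base_features(config$templates)
  specs <- variable_specs()
  m <- max(config$strides_per_run - 2L * config$n_trim, 1L)
  keep <- (config$n_trim + 1L):(config$n_trim + m)

  grid <- expand.grid(calibration = seq_len(config$n_calibrations),
                      run_i = seq_along(config$runs),
                      surface_i = seq_along(config$surfaces),
                      day = seq_len(config$n_days),
                      participant = seq_len(config$n_participants))
  n <- nrow(grid)
  out <- data.frame(participant = grid$participant,
                    day = grid$day,
                    surface = config$surfaces[grid$surface_i],
                    run = config$runs[grid$run_i],
                    calibration = grid$calibration)
  # average stride offsets over the retained strides, per run x signal
  so <- eff$stride_off
  d5 <- dim(so)
  stride_mean <- apply(so[, , , , keep, , drop = FALSE], c(1, 2, 3, 4, 6),
                       mean)
  dim(stride_mean) <- c(d5[1:4], d5[6])
  p <- grid$participant; d <- grid$day
  si <- grid$surface_i; ri <- grid$run_i; cc <- grid$calibration
  for (v in specs$name) {
    sg <- match(specs$signal[match(v, specs$name)], GAIT_SIGNALS)
    out[[v]] <- base[[v]] + eff$runner_off[cbind(p, sg)] +
      eff$day_off[cbind(p, d, si, sg)] + eff$cal_off[cbind(p, d, cc, sg)] +
      eff$run_off[cbind(p, d, si, ri, sg)] +
      stride_mean[cbind(p, d, si, ri, sg)]
  }
  out$RS <- eff$speed[p] + eff$speed_run[cbind(p, d, si, ri)] +
    eff$gate_noise[cbind(p, d, si, ri)]
  jit_mean <- apply(eff$jitter[, , , , keep, drop = FALSE], c(1, 2, 3, 4),
                    mean)
  dim(jit_mean) <- d5[1:4]
  out$SF <- eff$stride_freq[p] / (1 + jit_mean[cbind(p, d, si, ri)])
  out
}
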