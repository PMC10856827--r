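# Brute-force ICC(A,1) oracle: two-way ANOVA mean squares via stats::aov,
# independent of the package's sums-of-squares implementation.
icc_oracle_aov <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                   meas = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subj + meas, data = df))[[1]]
  rn <- trimws(rownames(tab))
  msr <- tab[rn == "subj", "Mean Sq"]
  msc <- tab[rn == "meas", "Mean Sq"]
  mse <- tab[rn == "Residuals", "Mean Sq"]
  n <- nrow(m)
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Small, fast study design used throughout the unit tests.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_participants = 3L, n_days = 2L, surfaces = "asphalt",
                   runs = c(1L, 3L), n_calibrations = 2L,
                   strides_per_run = 8L, n_trim = 2L, sample_rate = 120,
                   seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Variance-component matrix with chosen levels (all others zero).
vc_with <- function(runner = 0, day = 0, run = 0, calibration = 0,
                    stride = 0) {
  vc <- default_variance_components()
  vc[, "runner"] <- runner
  vc[, "day"] <- day
  vc[, "run"] <- run
  vc[, "calibration"] <- calibration
  vc[, "stride"] <- stride
  vc
}

# Components chosen so the analytic between-day ICC is exactly 0.8 and the
# within-day ICC exactly 0.95 (no stride-level noise):
# 4 / (4 + 0.55 + 0.25 + 0.2) = 0.8, (4 + 0.55 + 0.2) / 5 = 0.95.
vc_recovery <- function() {
  vc_with(runner = 4, day = 0.55, run = 0.25, calibration = 0.2, stride = 0)
}

# Minimal hand-built cycle_set for feature-extraction tests.
make_cycle_set <- function(waves, stride_frequency = 1.4, avg_speed = 3.4,
                           participant = 1, day = 1, surface = "asphalt",
                           run = 1, calibration = 1) {
  mean_wave <- vapply(waves, identity, numeric(101))
  structure(list(cycles = lapply(waves, function(w) matrix(w, 1, 101)),
                 mean = mean_wave, n_cycles_used = 1L, n_cycles_dropped = 0L,
                 stride_frequency = stride_frequency,
                 participant = participant, day = day, surface = surface,
                 run = run, calibration = calibration,
                 avg_speed = avg_speed),
            class = "cycle_set")
}

flat_waves <- function(value = 0) {
  w <- rep(value, 101)
  list(hip_flexion = w, hip_abduction = w, knee_flexion = w,
       ankle_dorsiflexion = w, ankle_eversion = w)
}
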