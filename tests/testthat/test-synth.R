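test_that("cohort has one recording per design cell and is seed-reproducible", {
  cfg <- tiny_config()
  co <- generate_cohort(cfg)
  expect_length(co$recordings, 3 * 2 * 1 * 2 * 2)
  keys <- vapply(co$recordings, function(r) {
    paste(r$participant, r$day, r$surface, r$run, r$calibration)
  }, character(1))
  expect_equal(anyDuplicated(keys), 0L)

  co2 <- generate_cohort(tiny_config())
  for (i in c(1L, 7L, length(co$recordings))) {
    expect_identical(co$recordings[[i]]$signals, co2$recordings[[i]]$signals)
    expect_identical(co$recordings[[i]]$avg_speed, co2$recordings[[i]]$avg_speed)
  }
  co3 <- generate_cohort(tiny_config(seed = 43L))
  expect_false(identical(co$recordings[[1]]$signals,
                         co3$recordings[[1]]$signals))
})

test_that("zero-variance cohort repeats a runner's recording across days, runs, calibrations", {
  cfg <- tiny_config(variance_components = vc_with())
  co <- generate_cohort(cfg)
  first <- co$recordings[[1]]
  for (rec in co$recordings) {
    if (rec$participant != first$participant) next
    expect_identical(rec$signals, first$signals)
  }
})

test_that("strides_per_run below 3 is rejected", {
  expect_error(tiny_config(strides_per_run = 2L), "strides_per_run")
  expect_error(tiny_config(variance_components = vc_with(runner = -1)),
               ">= 0")
})

test_that("analytic truth ICC follows the variance components", {
  cfg <- tiny_config(variance_components = vc_with(runner = 4, day = 1))
  expect_equal(truth_icc(cfg, "IHF", "between_day"), 0.8)
  expect_equal(truth_icc(cfg, "IHF", "within_day"), 1)
  expect_equal(truth_icc(cfg, "PKF", "calibration"), 1)

  cfg2 <- tiny_config(variance_components = vc_with(runner = 2, day = 2))
  expect_equal(truth_icc(cfg2, "IAD", "between_day"), 0.5)

  cfg3 <- tiny_config(variance_components = vc_with(runner = 9,
                                                    calibration = 1))
  expect_equal(truth_icc(cfg3, "PAE", "calibration"), 0.9)

  cfg4 <- tiny_config(variance_components = vc_with(runner = 1))
  for (ct in c("between_day", "within_day", "calibration")) {
    expect_equal(truth_icc(cfg4, "IHA", ct), 1)
  }
  expect_error(truth_icc(cfg, "NOPE", "between_day"), "unknown variable")
})

test_that("truth ICC stays within [0, 1] for random components and stride averaging", {
  set.seed(99)
  for (i in 1:25) {
    vc <- vc_with(runner = runif(1, 0, 5), day = runif(1, 0, 2),
                  run = runif(1, 0, 2), calibration = runif(1, 0, 2),
                  stride = runif(1, 0, 2))
    cfg <- tiny_config(variance_components = vc)
    for (ct in c("between_day", "within_day", "calibration")) {
      icc <- truth_icc(cfg, "IHF", ct)
      expect_gte(icc, 0)
      expect_lte(icc, 1)
    }
  }
  # larger stride averaging count raises every true ICC that involves
  # stride-differing noise
  vc <- vc_with(runner = 1, stride = 1)
  lo <- truth_icc(sim_config(strides_per_run = 5, n_trim = 1,
                             variance_components = vc),
                  "IHF", "between_day")
  hi <- truth_icc(sim_config(strides_per_run = 46, n_trim = 3,
                             variance_components = vc),
                  "IHF", "between_day")
  expect_gt(hi, lo)
})

test_that("true cycle boundaries are strictly increasing and cover the strides", {
  cfg <- tiny_config(period_jitter_frac = 0.01)
  co <- generate_cohort(cfg)
  b <- truth_boundaries(co$truth, 2, 1, "asphalt", 3)
  expect_length(b, cfg$strides_per_run + 1L)
  expect_true(all(diff(b) > 0))
  expect_error(truth_boundaries(co$truth, 99, 1, "asphalt", 1), "no such")
})

test_that("runner-level variance is recovered across many simulated runners", {
  cfg <- sim_config(n_participants = 5000L, n_days = 1L,
                    surfaces = "asphalt", runs = 1L, n_calibrations = 1L,
                    strides_per_run = 5L, n_trim = 1L,
                    variance_components = vc_with(runner = 4), seed = 5L)
  ft <- simulate_feature_table(cfg)
  expect_equal(var(ft$IHF), 4, tolerance = 0.05)
})

test_that("calibration copies of one run share stride-level noise exactly", {
  cfg <- tiny_config(variance_components = vc_with(stride = 2,
                                                   calibration = 1))
  co <- generate_cohort(cfg)
  recs <- co$recordings
  keys <- vapply(recs, function(r) {
    paste(r$participant, r$day, r$surface, r$run)
  }, character(1))
  for (k in unique(keys)) {
    pair <- recs[keys == k]
    expect_length(pair, 2L)
    sigs <- c("hip_flexion", "hip_abduction", "knee_flexion",
              "ankle_dorsiflexion", "ankle_eversion")
    d <- pair[[1]]$signals[, sigs] - pair[[2]]$signals[, sigs]
    # difference is the calibration offset: constant per channel
    expect_lt(max(apply(d, 2, function(col) diff(range(col)))), 1e-12)
    expect_identical(pair[[1]]$signals[, "foot_ap_position"],
                     pair[[2]]$signals[, "foot_ap_position"])
  }
})

test_that("fast feature simulation matches the waveform pipeline", {
  cfg <- tiny_config(strides_per_run = 10L, n_trim = 3L, sample_rate = 240)
  rep <- run_pipeline(cfg)
  ft <- simulate_feature_table(cfg)
  key <- function(d) paste(d$participant, d$day, d$surface, d$run,
                           d$calibration)
  i <- match(key(rep$features), key(ft))
  expect_false(anyNA(i))
  vars <- c("PHA", "PKF", "PAD", "PAE")  # peak variables: sub-sample phase
                                         # offsets do not move extrema
  for (v in vars) {
    expect_equal(rep$features[[v]], ft[[v]][i], tolerance = 0.05)
  }
  expect_equal(rep$features$RS, ft$RS[i], tolerance = 1e-10)
  expect_equal(rep$features$SF, ft$SF[i], tolerance = 0.02)
})
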