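test_that("comparison designs enumerate the study's measurement pairs", {
  bd <- build_design("between_day", n_days = 5)
  expect_length(bd$pairs, 5L)
  pairs <- t(vapply(bd$pairs, function(p) c(p$a$day, p$b$day), integer(2)))
  expect_equal(pairs, cbind(c(1:4, 5L), c(2:5, 2L)))
  for (p in bd$pairs) {
    expect_equal(p$a$run, 1L)
    expect_equal(p$a$calibration, 1L)
    expect_equal(p$b$calibration, 1L)
  }

  wd <- build_design("within_day", n_days = 5)
  expect_length(wd$pairs, 5L)
  for (d in 1:5) {
    expect_equal(wd$pairs[[d]]$a, list(day = d, run = 1L, calibration = 1L))
    expect_equal(wd$pairs[[d]]$b, list(day = d, run = 3L, calibration = 1L))
  }

  cal <- build_design("calibration", n_days = 5)
  expect_length(cal$pairs, 5L)
  for (d in 1:5) {
    expect_equal(cal$pairs[[d]]$a$calibration, 1L)
    expect_equal(cal$pairs[[d]]$b$calibration, 2L)
    expect_equal(cal$pairs[[d]]$a$run, cal$pairs[[d]]$b$run)
  }

  bd2 <- build_design("between_day", n_days = 2)
  expect_length(bd2$pairs, 1L)
  expect_equal(c(bd2$pairs[[1]]$a$day, bd2$pairs[[1]]$b$day), c(1L, 2L))
  expect_error(build_design("between_day", n_days = 1), "n_days")
})

test_that("ICC(A,1) matches hand-computed and oracle values", {
  m <- matrix(c(1, 3, 5, 7, 2, 4, 6, 8), 4, 2)
  fit <- icc_a1(m)
  expect_equal(fit$icc, 40 / 43, tolerance = 1e-12)  # frozen from the
  # sums-of-squares oracle: MSR = 40/3, MSC = 2, MSE = 0
  expect_equal(fit$mse, 0)
  expect_equal(fit$ms_rows, 40 / 3, tolerance = 1e-12)
  expect_equal(fit$ms_cols, 2, tolerance = 1e-12)

  two <- cbind(c(1, 5, 9), c(1, 5, 9))
  fit2 <- icc_a1(two)
  expect_equal(fit2$icc, 1)
  expect_equal(fit2$mse, 0)

  degenerate <- matrix(3, 4, 2)
  fit3 <- icc_a1(degenerate)
  expect_true(fit3$degenerate)
  expect_true(is.na(fit3$icc))

  expect_error(icc_a1(matrix(1:2, 1, 2)), "at least 2")
  expect_error(icc_a1(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("ICC(A,1) equals the brute-force ANOVA oracle on random matrices", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    m <- matrix(sample(-30:30, n * 2, replace = TRUE), n, 2)
    if (diff(range(m)) == 0) next
    expect_equal(icc_a1(m)$icc, icc_oracle_aov(m), tolerance = 1e-12)
  }
})

test_that("ICC(A,1) converges to the population value at large n", {
  set.seed(21)
  n <- 5000
  subj <- rnorm(n, 0, 2)
  m <- matrix(subj, n, 2) + matrix(rnorm(2 * n, 0, 1), n, 2)
  expect_equal(icc_a1(m)$icc, 0.8, tolerance = 0.02)  # 4 / (4 + 1)
})

test_that("ICC(A,1) honors absolute-agreement invariances", {
  set.seed(31)
  m <- matrix(rnorm(12, 10, 3), 6, 2)
  base <- icc_a1(m)$icc
  expect_equal(icc_a1(m + 7)$icc, base, tolerance = 1e-10)
  expect_equal(icc_a1(m * 3.5)$icc, base, tolerance = 1e-10)
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 2
  expect_lt(icc_a1(shifted)$icc, base)
})

test_that("SEM and MDC follow their closed forms", {
  expect_equal(sem_mdc(0), list(sem = 0, mdc = 0))
  expect_equal(sem_mdc(1)$mdc, 1.96 * sqrt(2), tolerance = 1e-12)
  out <- sem_mdc(4)
  expect_equal(out$sem, 2)
  expect_equal(out$mdc, 2 * 1.96 * sqrt(2), tolerance = 1e-12)
  expect_error(sem_mdc(-1), "mse")
  set.seed(5)
  for (mse in runif(20, 0, 50)) {
    out <- sem_mdc(mse)
    expect_equal(out$mdc / out$sem, 1.96 * sqrt(2), tolerance = 1e-12)
  }
})

test_that("reliability categories apply the conservative minimum rule", {
  expect_equal(categorize_icc(0.95, 0.76), "good")
  expect_equal(categorize_icc(0.90, 0.90), "excellent")
  expect_equal(categorize_icc(0.45, 0.10), "poor")
  expect_equal(categorize_icc(0.80, 0.80), "good")
  expect_equal(categorize_icc(0.60, 0.30), "poor")
  expect_equal(categorize_icc(0.92, 0.95), "excellent")
  expect_equal(categorize_icc(0.50, 0.50), "moderate")
})

test_that("error-free cohorts give perfect reliability everywhere", {
  cfg <- tiny_config(n_days = 3L,
                     variance_components = vc_with(runner = 4))
  ft <- simulate_feature_table(cfg)
  rel <- suppressMessages(run_reliability(ft))
  ang <- rel$summary[rel$summary$variable %in% c("IHF", "PKF", "PAE"), ]
  expect_true(all(abs(ang$icc_median - 1) < 1e-9))
  expect_true(all(ang$mdc_median < 1e-6))
  expect_true(all(ang$category == "excellent"))
})

test_that("calibration-only variance leaves within-day agreement perfect", {
  cfg <- tiny_config(n_days = 3L,
                     variance_components = vc_with(runner = 4,
                                                   calibration = 2))
  ft <- simulate_feature_table(cfg)
  rel <- suppressMessages(run_reliability(ft))
  s <- rel$summary[rel$summary$variable == "IKF", ]
  expect_equal(s$icc_median[s$type == "within_day"], 1, tolerance = 1e-9)
  expect_lt(s$icc_median[s$type == "calibration"], 1)
  expect_lt(s$icc_median[s$type == "between_day"], 1)
})

test_that("mdc/sem is exactly 1.96 sqrt(2) for every computed estimate", {
  cfg <- tiny_config(n_days = 3L, variance_components = vc_recovery())
  rel <- suppressMessages(run_reliability(simulate_feature_table(cfg)))
  ratio <- rel$pairs$mdc / rel$pairs$sem
  expect_true(all(abs(ratio[rel$pairs$sem > 0] - 1.96 * sqrt(2)) < 1e-12))
})

test_that("participants missing one measurement are excluded listwise with a log", {
  cfg <- tiny_config(n_participants = 4L, n_days = 3L,
                     variance_components = vc_recovery())
  ft <- simulate_feature_table(cfg)
  drop_row <- which(ft$participant == 2 & ft$day == 1 & ft$run == 1 &
                      ft$calibration == 1)
  ft <- ft[-drop_row, ]
  expect_message(rel <- run_reliability(ft, types = "between_day",
                                        variables = "IHF"),
                 "excluding 1 participant")
  pair12 <- rel$pairs[rel$pairs$pair == "1-2", ]
  expect_equal(pair12$n, 3L)
  pair23 <- rel$pairs[rel$pairs$pair == "2-3", ]
  expect_equal(pair23$n, 4L)
})

test_that("estimated ICCs recover the analytic truth over repeated cohorts", {
  bd <- wd <- numeric(60)
  for (i in seq_along(bd)) {
    cfg <- sim_config(n_participants = 17L, n_days = 5L,
                      surfaces = "asphalt", runs = c(1L, 3L),
                      n_calibrations = 1L,
                      variance_components = vc_recovery(),
                      seed = 7000L + i)
    rel <- suppressMessages(run_reliability(
      simulate_feature_table(cfg), types = c("between_day", "within_day"),
      variables = "PKF"))
    s <- rel$summary
    bd[i] <- s$icc_median[s$type == "between_day"]
    wd[i] <- s$icc_median[s$type == "within_day"]
  }
  expect_equal(mean(bd), 0.8, tolerance = 0.05)
  expect_equal(mean(wd), 0.95, tolerance = 0.05)
})
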