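#' Build the between-day difference matrix for one variable
#'
#' For every participant x day-to-day comparison (1-2, 2-3, 3-4, 4-5, 5-2)
#' x surface, the absolute difference of the variable, of running speed
#' (`RS`), and of stride frequency (`SF`) between the first runs of the two
#' days (calibration 1), plus the surface label. The canonical 17 x 5 x 2
#' design yields 170 rows.
#'
#' @param features Feature table.
#' @param variable Discrete variable to difference.
#' @param run Label of the analyzed run (first run of each day).
#' @return `data.frame` with columns `participant`, `day_pair`, `surface`,
#'   `abs_diff_angle` (deg), `abs_diff_speed` (m/s), `abs_diff_sf` (Hz).
#' @export
build_difference_matrix <- function(features, variable, run = NULL) {
  stopifnot(variable %in% names(features))
  if (is.null(run)) run <- min(features$run)
  n_days <- max(features$day)
  design <- build_design("between_day", n_days = n_days,
                         run_pair = c(run, run))
  surfaces <- sort(unique(features$surface))
  rows <- list()
  for (surf in surfaces) {
    feats <- features[features$surface == surf, ]
    for (pr in design$pairs) {
      a_v <- select_measurement(feats, pr$a, variable)
      b_v <- select_measurement(feats, pr$b, variable)
      a_rs <- select_measurement(feats, pr$a, "RS")
      b_rs <- select_measurement(feats, pr$b, "RS")
      a_sf <- select_measurement(feats, pr$a, "SF")
      b_sf <- select_measurement(feats, pr$b, "SF")
      ids <- Reduce(intersect, list(names(a_v), names(b_v)))
      if (!length(ids)) {
        stop(sprintf("no complete participants for pair %s on %s",
                     pr$label, surf))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant = ids, day_pair = pr$label, surface = surf,
        abs_diff_angle = abs(a_v[ids] - b_v[ids]),
        abs_diff_speed = abs(a_rs[ids] - b_rs[ids]),
        abs_diff_sf = abs(a_sf[ids] - b_sf[ids]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the random-intercept mixed model of between-day differences
#'
#' Restricted-maximum-likelihood fit of
#' `abs_diff_angle ~ abs_diff_speed + abs_diff_sf + surface + (1 | participant)`:
#' absolute between-day differences in a joint angle modeled by the absolute
#' between-day differences in running speed (deg per m/s) and stride
#' frequency (deg per 1/s) and the surface contrast (second surface level
#' minus the first, e.g. woodchip minus asphalt), with a random intercept
#' per runner cluster. Fixed-effect intervals and p-values use the
#' normal-approximation Wald method. The marginal R-squared is the variance
#' of the fixed-effect predictions over the total modeled variance (fixed +
#' random-intercept + residual).
#'
#' @param dm Difference matrix from [build_difference_matrix()].
#' @param conf_level Confidence level for the Wald intervals.
#' @return Object of class `mixed_model_result`: `coefficients`
#'   (`data.frame` with estimate, se, ci_lo, ci_hi, p per term),
#'   `var_intercept`, `var_residual`, `r2_marginal`, `singular`, and the
#'   underlying `lme4` fit as `model`.
#' @export
fit_mixed_model <- function(dm, conf_level = 0.95) {
  needed <- c("participant", "surface", "abs_diff_angle", "abs_diff_speed",
              "abs_diff_sf")
  stopifnot(all(needed %in% names(dm)))
  if (length(unique(dm$participant)) < 2) stop("need >= 2 runner clusters")
  dm <- as.data.frame(dm)
  dm$surface <- factor(dm$surface)
  two_surfaces <- nlevels(dm$surface) > 1
  form <- if (two_surfaces) {
    abs_diff_angle ~ abs_diff_speed + abs_diff_sf + surface + (1 | participant)
  } else {
    abs_diff_angle ~ abs_diff_speed + abs_diff_sf + (1 | participant)
  }
  fit <- suppressMessages(lme4::lmer(form, data = dm, REML = TRUE,
                                     control = lme4::lmerControl(
                                       check.conv.singular = "ignore")))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se),
                      ci_lo = unname(beta - z * se),
                      ci_hi = unname(beta + z * se),
                      p = unname(2 * pnorm(-abs(beta / se))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_int <- vc$vcov[vc$grp == "participant"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  X <- stats::model.matrix(fit)
  fixed_pred <- as.numeric(X %*% beta)
  var_fixed <- sum((fixed_pred - mean(fixed_pred))^2) / length(fixed_pred)
  r2m <- var_fixed / (var_fixed + var_int + var_res)
  structure(list(coefficients = coefs, var_intercept = var_int,
                 var_residual = var_res, r2_marginal = r2m,
                 singular = lme4::isSingular(fit), model = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("Random-intercept model: marginal R^2 = %.3f%s\n",
              x$r2_marginal,
              if (x$singular) " (singular random-effect fit)" else ""))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Fit the difference-matrix mixed model for every variable
#'
#' @param features Feature table.
#' @param variables Variables to model (defaults to the nine angle
#'   variables).
#' @return Named list of `mixed_model_result` objects.
#' @export
fit_all_mixed_models <- function(features, variables = ANGLE_VARIABLES) {
  setNames(lapply(variables, function(v) {
    fit_mixed_model(build_difference_matrix(features, v))
  }), variables)
}

#' Screen fitted models for significant coefficients
#'
#' Flags each variable's model when any fixed-effect predictor (speed,
#' stride-frequency, or surface difference; the intercept is not a
#' predictor) has `p < alpha`.
#'
#' @param results Named list of `mixed_model_result` objects (one per
#'   variable), e.g. from [fit_all_mixed_models()].
#' @param alpha Significance level.
#' @return `data.frame`: one row per variable with the marginal R-squared,
#'   each coefficient with its interval and p-value, and `significant`.
#' @export
significance_screen <- function(results, alpha = 0.05) {
  rows <- lapply(names(results), function(v) {
    res <- results[[v]]
    cf <- res$coefficients
    cf <- cf[cf$term != "(Intercept)", ]
    row <- data.frame(variable = v, r2_marginal = res$r2_marginal)
    for (i in seq_len(nrow(cf))) {
      term <- sub("^surface", "surface_", cf$term[i])
      row[[paste0(term, "_est")]] <- cf$estimate[i]
      row[[paste0(term, "_lo")]] <- cf$ci_lo[i]
      row[[paste0(term, "_hi")]] <- cf$ci_hi[i]
      row[[paste0(term, "_p")]] <- cf$p[i]
    }
    row$significant <- any(cf$p < alpha)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a difference matrix from the mixed model
#'
#' Draws data directly from the random-intercept model: per-row speed and
#' stride-frequency differences are absolute values of centred normals,
#' surfaces alternate over the canonical day-pair grid, runner intercepts
#' are normal with SD `sd_intercept`, and the response is the linear
#' predictor plus normal residuals. Used for estimator validation (fixed
#' effects, interval coverage, type-I error); responses may be negative,
#' unlike observed absolute differences.
#'
#' @param n_participants Number of runner clusters.
#' @param n_pairs Day-to-day comparisons per participant and surface.
#' @param surfaces Surface labels.
#' @param intercept Average intercept (deg).
#' @param b_speed,b_sf,b_surface True fixed effects (deg per m/s, deg per
#'   1/s, deg).
#' @param sd_intercept SD of the runner random intercept (deg).
#' @param sd_resid Residual SD (deg).
#' @param sd_speed_diff,sd_sf_diff SDs of the centred normals whose absolute
#'   values form the predictors.
#' @param seed Optional seed.
#' @return A difference-matrix `data.frame` plus attribute `truth` with the
#'   generating parameters.
#' @export
simulate_difference_matrix <- function(n_participants = 17L, n_pairs = 5L,
                                       surfaces = c("asphalt", "woodchip"),
                                       intercept = 1, b_speed = 4,
                                       b_sf = 0, b_surface = 0,
                                       sd_intercept = 1, sd_resid = 1,
                                       sd_speed_diff = 0.2,
                                       sd_sf_diff = 0.05,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(surface = surfaces, day_pair = seq_len(n_pairs),
                      participant = seq_len(n_participants),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  a_j <- rnorm(n_participants, 0, sd_intercept)
  x_speed <- abs(rnorm(n, 0, sd_speed_diff))
  x_sf <- abs(rnorm(n, 0, sd_sf_diff))
  x_surface <- as.numeric(grid$surface == surfaces[min(2, length(surfaces))])
  y <- intercept + a_j[grid$participant] + b_speed * x_speed + b_sf * x_sf +
    b_surface * x_surface + rnorm(n, 0, sd_resid)
  out <- data.frame(participant = grid$participant,
                    day_pair = paste0("pair", grid$day_pair),
                    surface = grid$surface,
                    abs_diff_angle = y, abs_diff_speed = x_speed,
                    abs_diff_sf = x_sf)
  attr(out, "truth") <- list(intercept = intercept, b_speed = b_speed,
                             b_sf = b_sf, b_surface = b_surface,
                             sd_intercept = sd_intercept,
                             sd_resid = sd_resid)
  out
}
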