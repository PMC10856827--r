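#' Build a comparison design
#'
#' The three comparison types each yield one measurement pair per testing
#' day (or day-to-day comparison):
#' * `between_day`: run 1 processed with calibration 1 on day pairs
#'   (1,2), (2,3), (3,4), (4,5), (5,2) for a five-day study. Day 5 is paired
#'   with day 2 to obtain a fifth comparison; for other `n_days >= 3` the
#'   design generalizes to consecutive pairs plus a final (n, 2) closure.
#' * `within_day`: the two analyzed runs of each day (study labels run 1 vs
#'   run 3), both processed with calibration 1.
#' * `calibration`: the first analyzed run of each day processed with
#'   calibration 1 vs calibration 2.
#'
#' @param type Comparison type.
#' @param n_days Number of testing days (>= 2).
#' @param run_pair Labels of the two analyzed runs within a day.
#' @return Object of class `comparison_design`: `type` and a list of
#'   `pairs`, each with selectors `a` and `b` (day, run, calibration).
#' @export
build_design <- function(type = c("between_day", "within_day", "calibration"),
                         n_days = 5L, run_pair = c(1L, 3L)) {
  type <- match.arg(type)
  if (n_days < 2) stop("need n_days >= 2")
  sel <- function(day, run, calibration) {
    list(day = as.integer(day), run = as.integer(run),
         calibration = as.integer(calibration))
  }
  if (type == "between_day") {
    day_pairs <- cbind(seq_len(n_days - 1L), seq_len(n_days - 1L) + 1L)
    if (n_days >= 3) day_pairs <- rbind(day_pairs, c(n_days, 2L))
    pairs <- lapply(seq_len(nrow(day_pairs)), function(i) {
      list(a = sel(day_pairs[i, 1L], run_pair[1L], 1L),
           b = sel(day_pairs[i, 2L], run_pair[1L], 1L),
           label = paste0(day_pairs[i, 1L], "-", day_pairs[i, 2L]))
    })
  } else if (type == "within_day") {
    if (length(run_pair) < 2) stop("within_day design needs two run labels")
    pairs <- lapply(seq_len(n_days), function(d) {
      list(a = sel(d, run_pair[1L], 1L), b = sel(d, run_pair[2L], 1L),
           label = paste0("day", d))
    })
  } else {
    pairs <- lapply(seq_len(n_days), function(d) {
      list(a = sel(d, run_pair[1L], 1L), b = sel(d, run_pair[1L], 2L),
           label = paste0("day", d))
    })
  }
  structure(list(type = type, n_days = as.integer(n_days), pairs = pairs),
            class = "comparison_design")
}

#' @export
print.comparison_design <- function(x, ...) {
  cat(sprintf("Comparison design '%s': %d pairs\n", x$type, length(x$pairs)))
  for (p in x$pairs) {
    cat(sprintf("  %s: (day %d, run %d, cal %d) vs (day %d, run %d, cal %d)\n",
                p$label, p$a$day, p$a$run, p$a$calibration,
                p$b$day, p$b$run, p$b$calibration))
  }
  invisible(x)
}

#' Intraclass correlation ICC(A,1) for absolute agreement
#'
#' Two-way random-effects single-measurement ICC for absolute agreement,
#' computed from the mean squares of the two-way ANOVA of an
#' `n subjects x k measurements` matrix:
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`,
#' with `MSR`, `MSC`, `MSE` the rows (subjects), columns (measurements), and
#' error mean squares. Negative estimates are returned as computed, never
#' clipped.
#'
#' @param m Numeric matrix, rows = subjects (`n >= 2`), columns = repeated
#'   measurements (`k >= 2`), no missing cells.
#' @return List: `icc`, `ms_rows`, `ms_cols`, `mse`, `n`, `k`, and
#'   `degenerate` (`TRUE` when the matrix has zero total variance, in which
#'   case `icc` is `NA`).
#' @export
icc_a1 <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("icc_a1 requires a complete matrix")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 measurements")
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- max(ss_total - ss_rows - ss_cols, 0)
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_total <= 1e-12 * max(1, grand^2)) {
    return(list(icc = NA_real_, ms_rows = ms_rows, ms_cols = ms_cols,
                mse = mse, n = n, k = k, degenerate = TRUE))
  }
  icc <- (ms_rows - mse) /
    (ms_rows + (k - 1) * mse + (k / n) * (ms_cols - mse))
  list(icc = icc, ms_rows = ms_rows, ms_cols = ms_cols, mse = mse,
       n = n, k = k, degenerate = FALSE)
}

#' Standard error of measurement and minimal detectable change
#'
#' `SEM = sqrt(MSE)` of the repeated-measures ANOVA underlying the ICC;
#' `MDC = 1.96 * SEM * sqrt(2)`, the smallest change exceeding measurement
#' error with 95% confidence.
#'
#' @param mse Mean squared error (>= 0).
#' @return List with `sem` and `mdc` (same units as the measurements).
#' @export
sem_mdc <- function(mse) {
  if (!is.finite(mse) || mse < 0) stop("mse must be finite and >= 0")
  sem <- sqrt(mse)
  list(sem = sem, mdc = 1.96 * sem * sqrt(2))
}

#' Categorize reliability from the median and minimum ICC
#'
#' Cut-offs: ICC < 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good, >= 0.9
#' excellent. When the minimum ICC across comparisons falls into a lower
#' category than the median, the lower (conservative) category is reported.
#'
#' @param icc_median Median ICC across comparison pairs.
#' @param icc_min Minimum ICC across comparison pairs.
#' @return Category label (character).
#' @export
categorize_icc <- function(icc_median, icc_min = icc_median) {
  stopifnot(is.finite(icc_median), is.finite(icc_min))
  one <- function(icc) {
    if (icc < 0.5) "poor"
    else if (icc < 0.75) "moderate"
    else if (icc < 0.9) "good"
    else "excellent"
  }
  levels <- c("poor", "moderate", "good", "excellent")
  levels[min(match(one(icc_median), levels), match(one(icc_min), levels))]
}

# Extract the values of `variable` for one design selector, ordered by
# participant; returns a named vector (participant -> value).
select_measurement <- function(features, selector, variable) {
  rows <- features$day == selector$day & features$run == selector$run &
    features$calibration == selector$calibration
  sub <- features[rows, c("participant", variable)]
  setNames(sub[[variable]], sub$participant)
}

#' Run the full reliability analysis
#'
#' For every variable x surface x comparison type, computes per-pair
#' ICC(A,1), SEM, and MDC from the `n_participants x 2` matrix of that
#' pair's measurements, plus the mean and SD of the absolute pairwise
#' differences; aggregates across the pairs as median \[min, max\] ICC,
#' median MDC, and the conservative reliability category. Participants with
#' a missing value in either measurement of a pair are excluded listwise
#' from that pair (logged via `message()`).
#'
#' Running speed and stride frequency are included for between-day and
#' within-day comparisons; the calibration comparison re-processes the same
#' run, for which they are not applicable.
#'
#' @param features Feature table (see [build_feature_table()]).
#' @param types Comparison types to analyze.
#' @param variables Variables to analyze; defaults to the nine angle
#'   variables plus `RS` and `SF`.
#' @param run_pair Labels of the two analyzed runs (defaults to the two
#'   smallest run labels present).
#' @return Object of class `reliability_results`: `pairs` (per-pair long
#'   table) and `summary` (aggregates per variable x surface x type).
#' @export
run_reliability <- function(features,
                            types = c("between_day", "within_day",
                                      "calibration"),
                            variables = c(ANGLE_VARIABLES, "RS", "SF"),
                            run_pair = NULL) {
  stopifnot(all(KEY_COLUMNS %in% names(features)))
  n_days <- max(features$day)
  if (is.null(run_pair)) run_pair <- sort(unique(features$run))[1:2]
  surfaces <- sort(unique(features$surface))
  has_cal2 <- any(features$calibration == 2)

  pair_rows <- list()
  sum_rows <- list()
  for (type in types) {
    if (type == "calibration" && !has_cal2) next
    design <- build_design(type, n_days = n_days, run_pair = run_pair)
    vars <- if (type == "calibration") {
      setdiff(variables, c("RS", "SF"))
    } else variables
    for (surf in surfaces) {
      feats <- features[features$surface == surf, ]
      for (v in vars) {
        per_pair <- lapply(design$pairs, function(pr) {
          a <- select_measurement(feats, pr$a, v)
          b <- select_measurement(feats, pr$b, v)
          ids <- intersect(names(a), names(b))
          if (length(ids) < length(union(names(a), names(b)))) {
            message(sprintf(
              "%s/%s/%s pair %s: excluding %d participant(s) without both measurements",
              type, surf, v, pr$label,
              length(union(names(a), names(b))) - length(ids)))
          }
          if (length(ids) < 2) {
            stop(sprintf("pair %s (%s, %s, %s): fewer than 2 complete participants",
                         pr$label, type, surf, v))
          }
          mat <- cbind(a[ids], b[ids])
          fit <- icc_a1(mat)
          sm <- sem_mdc(fit$mse)
          adiff <- abs(mat[, 1L] - mat[, 2L])
          data.frame(variable = v, surface = surf, type = type,
                     pair = pr$label, n = fit$n, icc = fit$icc,
                     ms_rows = fit$ms_rows, ms_cols = fit$ms_cols,
                     mse = fit$mse, sem = sm$sem, mdc = sm$mdc,
                     mean_abs_diff = mean(adiff), sd_abs_diff = sd(adiff),
                     degenerate = fit$degenerate)
        })
        per_pair <- do.call(rbind, per_pair)
        pair_rows[[length(pair_rows) + 1L]] <- per_pair
        iccs <- per_pair$icc
        degen <- all(is.na(iccs))
        if (degen) {
          icc_med <- icc_min <- icc_max <- NA_real_
          category <- NA_character_
        } else {
          icc_med <- median(iccs, na.rm = TRUE)
          icc_min <- min(iccs, na.rm = TRUE)
          icc_max <- max(iccs, na.rm = TRUE)
          category <- categorize_icc(icc_med, icc_min)
        }
        sum_rows[[length(sum_rows) + 1L]] <- data.frame(
          variable = v, surface = surf, type = type,
          n_pairs = nrow(per_pair),
          icc_median = icc_med, icc_min = icc_min, icc_max = icc_max,
          mdc_median = median(per_pair$mdc),
          mean_abs_diff = mean(per_pair$mean_abs_diff),
          sd_abs_diff = sd_pooled_abs(per_pair),
          category = category)
      }
    }
  }
  structure(list(pairs = do.call(rbind, pair_rows),
                 summary = do.call(rbind, sum_rows)),
            class = "reliability_results")
}

# SD of the absolute differences pooled across a design's pairs, from the
# per-pair means/SDs and counts (equal-n exact pooling of the second moment).
sd_pooled_abs <- function(per_pair) {
  n <- per_pair$n
  mu <- per_pair$mean_abs_diff
  s2 <- per_pair$sd_abs_diff^2
  total_n <- sum(n)
  grand <- sum(n * mu) / total_n
  ss <- sum((n - 1) * s2 + n * (mu - grand)^2)
  sqrt(ss / (total_n - 1))
}

#' @export
print.reliability_results <- function(x, ...) {
  cat("Reliability results:\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
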