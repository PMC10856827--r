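#' Run the full pipeline on a synthetic cohort (or supplied recordings)
#'
#' Executes generation (optional), segmentation, feature extraction,
#' reliability analysis, and the mixed-model association analysis, and
#' assembles all result tables plus a comparison of estimated against true
#' ICCs when simulation truth is available. Regeneration from the same
#' configuration (and hence seed) is bit-identical.
#'
#' @param config A [sim_config()]; ignored when `recordings` is supplied
#'   except for `n_trim`.
#' @param recordings Optional list of `session_recording` objects (e.g. from
#'   [read_cohort()]); when `NULL` a cohort is generated from `config`.
#' @param truth Optional `simulation_truth` matching `recordings`.
#' @param n_trim Cycles trimmed from each end of every recording.
#' @return Object of class `pipeline_report`: `features`, `reliability`,
#'   `mixed_models`, `model_screen`, `truth_comparison` (or `NULL`), `qc`
#'   (per-recording cycle counts), and `config`.
#' @export
run_pipeline <- function(config = sim_config(), recordings = NULL,
                         truth = NULL, n_trim = config$n_trim) {
  if (is.null(recordings)) {
    cohort <- generate_cohort(config)
    recordings <- cohort$recordings
    truth <- cohort$truth
  }
  cycle_sets <- vector("list", length(recordings))
  qc <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    cs <- tryCatch(
      suppressMessages(segment_recording(rec, n_trim = n_trim)),
      error = function(e) {
        stop(sprintf(
          "segmentation failed for participant %s day %d %s run %d calibration %d: %s",
          rec$participant, rec$day, rec$surface, rec$run, rec$calibration,
          conditionMessage(e)), call. = FALSE)
      })
    cycle_sets[[i]] <- cs
    qc[[i]] <- data.frame(participant = rec$participant, day = rec$day,
                          surface = rec$surface, run = rec$run,
                          calibration = rec$calibration,
                          n_cycles_used = cs$n_cycles_used,
                          n_cycles_dropped = cs$n_cycles_dropped,
                          stride_frequency = cs$stride_frequency)
  }
  features <- build_feature_table(cycle_sets)
  reliability <- suppressMessages(run_reliability(features))
  # the mixed model needs enough difference rows to support its runner
  # clusters; skip it for very small designs
  n_pairs <- length(build_design("between_day", n_days = max(features$day))$pairs)
  dm_rows <- length(unique(features$participant)) * n_pairs *
    length(unique(features$surface))
  fit_models <- dm_rows >= 10 &&
    dm_rows >= 2 * length(unique(features$participant))
  models <- if (fit_models) fit_all_mixed_models(features) else NULL
  screen <- if (fit_models) significance_screen(models) else NULL

  truth_cmp <- NULL
  if (!is.null(truth)) {
    s <- reliability$summary
    s <- s[s$variable %in% ANGLE_VARIABLES, ]
    truth_cmp <- data.frame(variable = s$variable, surface = s$surface,
                            type = s$type, icc_median = s$icc_median)
    truth_cmp$true_icc <- mapply(function(v, ct) truth_icc(truth, v, ct),
                                 truth_cmp$variable, truth_cmp$type)
    truth_cmp$abs_error <- abs(truth_cmp$icc_median - truth_cmp$true_icc)
  }
  structure(list(features = features, reliability = reliability,
                 mixed_models = models, model_screen = screen,
                 truth_comparison = truth_cmp,
                 qc = do.call(rbind, qc), config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d feature rows, %d reliability estimates\n",
              nrow(x$features), nrow(x$reliability$summary)))
  if (!is.null(x$truth_comparison)) {
    cat(sprintf("  max |estimated - true| ICC: %.3f\n",
                max(x$truth_comparison$abs_error)))
  }
  invisible(x)
}

# "median [min, max]" strings in a wide variable x surface layout, one
# column block per comparison type.
format_icc_table <- function(summary) {
  s <- summary
  s$icc_text <- sprintf("%.2f [%.2f, %.2f]", s$icc_median, s$icc_min,
                        s$icc_max)
  out <- unique(s[, c("variable", "surface")])
  for (type in unique(s$type)) {
    block <- s[s$type == type, ]
    i <- match(paste(out$variable, out$surface),
               paste(block$variable, block$surface))
    out[[paste0(type, "_icc")]] <- block$icc_text[i]
    out[[paste0(type, "_category")]] <- block$category[i]
  }
  rownames(out) <- NULL
  out
}

#' Write all report tables as CSV plus a plain-text summary
#'
#' Writes `icc_table.csv` (median \[min, max\] ICC and category per variable
#' x surface x comparison type), `mdc_table.csv`, `abs_diff_table.csv`
#' (mean and SD of absolute differences), `reliability_pairs.csv` (per-pair
#' detail), `mixed_models.csv`, `qc_log.csv`, `truth_comparison.csv` when
#' available, and `summary.txt`.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- report$reliability$summary
  w <- function(x, f) data.table::fwrite(x, file.path(dir, f))
  w(format_icc_table(s), "icc_table.csv")
  w(s[, c("variable", "surface", "type", "mdc_median")], "mdc_table.csv")
  w(s[, c("variable", "surface", "type", "mean_abs_diff", "sd_abs_diff")],
    "abs_diff_table.csv")
  w(report$reliability$pairs, "reliability_pairs.csv")
  if (!is.null(report$model_screen)) {
    w(report$model_screen, "mixed_models.csv")
  }
  w(report$qc, "qc_log.csv")
  if (!is.null(report$truth_comparison)) {
    w(report$truth_comparison, "truth_comparison.csv")
  }
  lines <- c(
    "Gait-kinematics reliability pipeline summary",
    sprintf("feature rows: %d", nrow(report$features)),
    sprintf("reliability estimates: %d", nrow(s)),
    sprintf("cycles used per run: median %d",
            as.integer(median(report$qc$n_cycles_used))))
  if (!is.null(report$model_screen)) {
    lines <- c(lines, sprintf("mixed models flagged significant: %d of %d",
                              sum(report$model_screen$significant),
                              nrow(report$model_screen)))
  }
  if (!is.null(report$truth_comparison)) {
    lines <- c(lines, sprintf("max |estimated - true| ICC: %.3f",
                              max(report$truth_comparison$abs_error)))
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' Expected precision of an ICC(A,1) estimate at a given design
#'
#' Monte-Carlo planning utility: simulates `n x k` measurement matrices with
#' between-subject variance `true_icc` and error variance `1 - true_icc`
#' (so the population ICC equals `true_icc`), estimates ICC(A,1) on each,
#' and returns half the spread between the 2.5th and 97.5th percentiles of
#' the estimates — the expected half-width of a 95% confidence interval at
#' that design.
#'
#' @param n Number of subjects (>= 2).
#' @param k Measurements per subject (>= 2).
#' @param true_icc True ICC in (0, 1).
#' @param n_sim Number of simulated matrices.
#' @param seed Optional seed.
#' @return List: `half_width`, the quantiles `lo`/`hi`, and the mean
#'   estimate.
#' @export
icc_precision <- function(n, k, true_icc, n_sim = 2000L, seed = NULL) {
  stopifnot(n >= 2, k >= 2, true_icc > 0, true_icc < 1, n_sim >= 2)
  if (!is.null(seed)) set.seed(seed)
  sd_subj <- sqrt(true_icc)
  sd_err <- sqrt(1 - true_icc)
  est <- vapply(seq_len(n_sim), function(i) {
    subj <- rnorm(n, 0, sd_subj)
    m <- matrix(subj, n, k) + matrix(rnorm(n * k, 0, sd_err), n, k)
    icc_a1(m)$icc
  }, numeric(1))
  q <- quantile(est, c(0.025, 0.975), names = FALSE)
  list(half_width = (q[2L] - q[1L]) / 2, lo = q[1L], hi = q[2L],
       mean_estimate = mean(est))
}
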