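#!/usr/bin/env Rscript
# Stage 4: reliability analysis. Between-day, within-day, and calibration
# ICC(A,1), SEM, and MDC per variable and surface, aggregated as median
# [min, max] across the five comparison pairs with conservative
# categorization, plus the absolute-difference summaries.

suppressPackageStartupMessages(library(gaitrel))

out_dir <- "results"
path <- file.path(out_dir, "feature_table.csv")
if (!file.exists(path)) stop("run analysis/03_features.R first")
features <- read_feature_table(path)

rel <- run_reliability(features)
s <- rel$summary

write.csv(s, file.path(out_dir, "tables", "reliability_summary.csv"),
          row.names = FALSE)
write.csv(rel$pairs, file.path(out_dir, "tables", "reliability_pairs.csv"),
          row.names = FALSE)

cat("Median ICC [range] per comparison type (asphalt, angle variables):\n")
ang <- s[s$surface == "asphalt" &
           !s$variable %in% c("RS", "SF"), ]
for (type in unique(ang$type)) {
  block <- ang[ang$type == type, ]
  cat(sprintf("  %-12s median of medians %.2f, categories: %s\n", type,
              median(block$icc_median),
              paste(sort(unique(block$category)), collapse = "/")))
}

bd <- s$mean_abs_diff[s$type == "between_day" & !s$variable %in% c("RS", "SF")]
wd <- s$mean_abs_diff[s$type == "within_day" & !s$variable %in% c("RS", "SF")]
cat(sprintf("\nBetween-day vs within-day mean absolute difference ratio: %.2f\n",
            mean(bd) / mean(wd)))
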