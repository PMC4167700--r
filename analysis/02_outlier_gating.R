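#!/usr/bin/env Rscript
# Ellipse-gate the simulated cohorts and compare outlier rates.
#
# Gates each (manufacturer x sex) stratum on (log QT, log RR) at 99.9%
# coverage, writes inlier tables for the downstream fits, the outlier
# bookkeeping, and Fisher exact tests on the between-device outlier
# rates per sex.

library(qtcohort)

dir.create("scratch/cohorts", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

summaries <- list()
for (p in c("fukuda_log", "nihon_log", "combined_log", "combined_raw")) {
  tab <- read_interval_csv(file.path("scratch/cohorts",
                                     paste0(p, ".csv")), units = "ms")
  scale <- if (grepl("raw", p)) "raw" else "log"
  gt <- apply_gate(tab, scale = scale, coverage = 0.999,
                   stratify = "stratum")
  write_interval_csv(gt$inliers,
                     file.path("scratch/cohorts",
                               paste0(p, "_inliers.csv")), units = "ms")
  gt$summary$preset <- p
  summaries[[p]] <- gt$summary
}
all_sum <- do.call(rbind, summaries)
write.table(format(all_sum, digits = 4), "results/02_outlier_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Per-stratum outlier rates (ellipse gate, 99.9% coverage):\n")
print(all_sum[, c("preset", "manufacturer", "sex", "n_before",
                  "n_outliers", "pct_outliers")],
      digits = 3, row.names = FALSE)

# Between-device Fisher tests on the combined log-gated cohort
cmb <- summaries$combined_log
rows <- list()
for (sx in c("male", "female")) {
  a <- cmb[cmb$manufacturer == "NihonKohden" & cmb$sex == sx, ]
  b <- cmb[cmb$manufacturer == "FukudaDenshi" & cmb$sex == sx, ]
  rows[[sx]] <- data.frame(
    sex = sx, rate_nk = a$pct_outliers, rate_fd = b$pct_outliers,
    p = fisher_exact_outliers(a$n_outliers, a$n_before,
                              b$n_outliers, b$n_before))
}
fish <- do.call(rbind, rows)
write.table(format(fish, digits = 4), "results/02_fisher_outliers.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nFisher exact tests on outlier rates (NK vs FD):\n")
print(fish, digits = 3, row.names = FALSE)
cat("\nUnder the generator both devices share the same gate geometry,",
    "so rates hover near the nominal 0.1% and the tests are null;",
    "with the study's reconstructed counts (275/42,673 vs 36/8,631)",
    "the same test gives p:",
    format(fisher_exact_outliers(275, 42673, 36, 8631), digits = 3),
    "\n")
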