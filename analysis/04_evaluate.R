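#!/usr/bin/env Rscript
# Evaluation of the selected models: test metrics, ROC curves, the FIT
# baseline on the same records, and polyp-score distribution summaries.
#
# Reads:  results/cohort.csv, scratch/fit.rds
# Writes: results/metrics_<sex>.json, results/roc_<sex>.csv,
#         results/fit_comparison.csv, results/score_summary.csv

library(polypkde)
if (!file.exists("scratch/fit.rds")) {
  stop("run analysis/03_fit_grid.R first (scratch/fit.rds missing)")
}
fit <- readRDS("scratch/fit.rds")
cohort <- read_cohort_csv("results/cohort.csv")

report <- report_pipeline(fit, cohort, seed = 11)

fit_rows <- list(); sum_rows <- list()
for (sx in names(report)) {
  r <- report[[sx]]
  write_metrics_json(r$metrics, sprintf("results/metrics_%s.json", sx))
  write.csv(r$roc, sprintf("results/roc_%s.csv", sx), row.names = FALSE)
  for (scope in c("test", "all")) {
    m <- r[[paste0("fit_baseline_", scope)]]
    fit_rows[[length(fit_rows) + 1]] <- data.frame(
      sex = sx, predictor = "FIT", scope = scope, sensitivity = m$sensitivity,
      specificity = m$specificity, mcc = m$mcc)
  }
  fit_rows[[length(fit_rows) + 1]] <- data.frame(
    sex = sx, predictor = r$best_name, scope = "test",
    sensitivity = r$metrics$sensitivity, specificity = r$metrics$specificity,
    mcc = r$metrics$mcc)
  for (cell in names(r$score_summary$by_cell)) {
    s <- r$score_summary$by_cell[[cell]]
    sum_rows[[length(sum_rows) + 1]] <- data.frame(
      sex = sx, cell = cell, count = s$count,
      q1 = s$quartiles[1], median = s$quartiles[2], q3 = s$quartiles[3])
  }
  message(sprintf(
    "%s: model %s test MCC %.3f vs FIT MCC %.3f (test records)",
    sx, r$best_name, r$metrics$mcc,
    report[[sx]]$fit_baseline_test$mcc))
}
write.csv(do.call(rbind, fit_rows), "results/fit_comparison.csv",
          row.names = FALSE)
write.csv(do.call(rbind, sum_rows), "results/score_summary.csv",
          row.names = FALSE)
message("wrote metrics, ROC, FIT comparison and score summaries under results/")
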