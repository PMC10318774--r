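#' Prepare a cohort for modelling
#'
#' Applies, in order, the per-feature discard limits and the eligibility
#' filter, then splits the eligible records by sex.
#'
#' @param records a cohort `data.frame`.
#' @param schema feature schema.
#' @return list with `male`, `female` (record subsets), `flow`
#'   (cohort-flow counts) and `discarded` (per-feature discard counts).
#' @export
prepare_cohort <- function(records, schema = default_schema()) {
  kept <- apply_discard_limits(records, schema)
  elig <- apply_eligibility(kept)
  rec <- elig$eligible
  list(
    male = rec[rec$sex == "male", , drop = FALSE],
    female = rec[rec$sex == "female", , drop = FALSE],
    flow = elig$flow,
    discarded = attr(kept, "discarded")
  )
}

#' End-to-end fit: cohort preparation, grid, best-model selection
#'
#' Runs [prepare_cohort()], then per requested sex [run_grid()] and
#' [select_best()]. This is the programmatic form of the pipeline the
#' analysis scripts drive.
#'
#' @param records a cohort `data.frame` (e.g. from [generate_cohort()]).
#' @param sexes which sexes to fit (`"male"`, `"female"` or both).
#' @param k finalists evaluated on the test split.
#' @param ... passed to [run_grid()] (thresholds, modes, exponents,
#'   classifiers, eliminate, seed, ...).
#' @param schema feature schema.
#' @return list of class `pipeline_fit`: per sex, the `grid` and the
#'   [select_best()] result; plus `flow`.
#' @export
fit_pipeline <- function(records, sexes = c("male", "female"), k = 6,
                         schema = default_schema(), ...) {
  prep <- prepare_cohort(records, schema)
  out <- list(flow = prep$flow, sexes = list())
  for (sx in sexes) {
    grid <- run_grid(prep[[sx]], schema = schema, ...)
    out$sexes[[sx]] <- list(grid = grid, selection = select_best(grid, k = k))
  }
  class(out) <- "pipeline_fit"
  out
}

#' Evaluation and attribution report for a fitted pipeline
#'
#' For each fitted sex: test metrics of the best model, its ROC curve,
#' the FIT baseline on the same test records and on all eligible records,
#' the Kruskal-Wallis feature screen, polyp-score distribution summaries,
#' and Shapley feature importance on the test split.
#'
#' @param fit a `pipeline_fit`.
#' @param records the cohort the fit was produced from.
#' @param n_shap_explain cap on explained test rows for attribution.
#' @param seed attribution seed.
#' @param schema feature schema.
#' @return list per sex with `metrics`, `roc`, `fit_baseline_test`,
#'   `fit_baseline_all`, `kruskal`, `score_summary`, `attribution`.
#' @export
report_pipeline <- function(fit, records, n_shap_explain = 50, seed = 1,
                            schema = default_schema()) {
  prep <- prepare_cohort(records, schema)
  out <- list()
  for (sx in names(fit$sexes)) {
    sel <- fit$sexes[[sx]]$selection
    best <- sel$best
    sp <- fit$sexes[[sx]]$grid$splits[[as.character(best$threshold_mm)]]
    sc <- predict_polyp_score(best, sp$test$x)
    pred <- ifelse(sc >= 0.5, "yes", "no")
    rec_sx <- prep[[sx]]
    test_rec <- rec_sx[match(sp$test$patient_id, rec_sx$patient_id), ,
                       drop = FALSE]
    expl <- sp$test$x[seq_len(min(n_shap_explain, nrow(sp$test$x))), ,
                      drop = FALSE]
    out[[sx]] <- list(
      best_name = best$name,
      metrics = sel$metrics,
      roc = roc_auc(sp$test$y, sc)$curve,
      fit_baseline_test = fit_baseline_metrics(test_rec, best$threshold_mm,
                                               schema),
      fit_baseline_all = fit_baseline_metrics(rec_sx, best$threshold_mm,
                                              schema),
      kruskal = kruskal_screen(make_labels(rec_sx, best$threshold_mm,
                                           schema)),
      score_summary = score_distribution_summary(sc, sp$test$y, pred),
      attribution = shapley_importance(best, sp$train$x, expl, seed = seed)
    )
  }
  out
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seeds and package versions sufficient to
#' reproduce a run's outputs exactly.
#'
#' @param path output JSON path.
#' @param config named list of run configuration.
#' @export
write_manifest <- function(path, config) {
  manifest <- list(
    config = config,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("polypkde")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
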