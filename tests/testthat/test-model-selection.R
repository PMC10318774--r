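test_that("every classifier in the zoo fits, scores in [0,1] deterministically", {
  ds <- planted_dataset(n = 120, delta = 1.5, seed = 10)
  for (id in classifier_zoo()) {
    cl <- fit_classifier(id, ds$x, ds$y, seed = 3)
    s1 <- predict_polyp_score(cl, ds$x)
    s2 <- predict_polyp_score(cl, ds$x)
    expect_identical(s1, s2)
    expect_true(all(s1 >= 0 & s1 <= 1), label = id)
    # a strong planted signal should be learnable above chance by everyone
    expect_gt(roc_auc(ds$y, s1)$auc, 0.6)
  }
})

test_that("a perfectly separated toy set yields non-overlapping class scores", {
  x <- data.frame(a = c(rep(0, 10), rep(5, 10)))
  y <- factor(rep(c("no", "yes"), each = 10), levels = c("no", "yes"))
  cl <- fit_classifier("logistic_regression", x, y)
  s <- predict_polyp_score(cl, x)
  expect_gt(min(s[y == "yes"]), max(s[y == "no"]))
})

test_that("decision-function scaling is monotone and clamped", {
  ds <- planted_dataset(n = 100, delta = 1, seed = 2)
  cl <- fit_classifier("linear_svc", ds$x, ds$y, seed = 1)
  raw <- polypkde:::raw_score(cl, ds$x)
  s <- predict_polyp_score(cl, ds$x)
  expect_equal(order(raw), order(s))
  expect_true(all(s >= 0 & s <= 1))
  # new points beyond the training extremes clamp to [0,1]
  far <- ds$x
  far[1, ] <- far[1, ] + 100
  expect_true(all(predict_polyp_score(cl, far) <= 1))
})

test_that("cross-validated MCC equals a fold-by-fold recomputation", {
  ds <- planted_dataset(n = 150, seed = 12)
  res <- cv_mcc(ds, "lda", transform_spec("kde", 2),
                schema = planted_schema(), seed = 7)
  fp <- res$fold_predictions
  recomputed <- vapply(sort(unique(fp$fold)), function(fo) {
    sub <- fp[fp$fold == fo, ]
    metrics_report(sub$truth, sub$prediction)$mcc
  }, numeric(1))
  expect_equal(res$per_fold, recomputed, tolerance = 1e-12)
  expect_equal(res$mean, mean(recomputed), tolerance = 1e-12)
})

test_that("backward elimination yields a strictly nested path of the right length", {
  ds <- planted_dataset(n = 150, p_info = 2, p_noise = 3, delta = 1, seed = 8)
  path <- backward_eliminate(ds, "logistic_regression", transform_spec("none"),
                             schema = planted_schema(), seed = 3)
  expect_length(path, 5 - 3 + 1)
  sizes <- vapply(path, function(c) length(c$features), numeric(1))
  expect_equal(sizes, c(5, 4, 3))
  for (i in 2:length(path)) {
    expect_true(all(path[[i]]$features %in% path[[i - 1]]$features))
  }
  # p = floor input: single candidate, no elimination
  ds3 <- ds
  ds3$x <- ds$x[, 1:3]
  single <- backward_eliminate(ds3, "logistic_regression",
                               transform_spec("none"),
                               schema = planted_schema(), seed = 3)
  expect_length(single, 1)
  expect_equal(single[[1]]$features, names(ds3$x))
})

test_that("strong planted features survive elimination to the floor", {
  ds <- planted_dataset(n = 400, p_info = 2, p_noise = 3, delta = 1.5,
                        seed = 44)
  path <- backward_eliminate(ds, "logistic_regression", transform_spec("none"),
                             schema = planted_schema(), seed = 1)
  final <- path[[length(path)]]$features
  expect_true(all(c("info1", "info2") %in% final))
})

test_that("the grid enumerates cells correctly and skips empty classes", {
  ds_rec <- generate_cohort(synthetic_spec(n_male = 160, n_female = 0,
                                           seed = 5))
  g <- run_grid(ds_rec, thresholds = 0, modes = "none",
                classifiers = c("logistic_regression", "lda"), seed = 2)
  expect_equal(nrow(g$table), 2)
  expect_true(all(is.na(g$table$exponent)))
  g2 <- run_grid(ds_rec, thresholds = 0, modes = c("none", "kde",
                                                   "sigmoid_kde"),
                 exponents = 1:2, classifiers = "lda", seed = 2)
  expect_equal(nrow(g2$table), 1 + 2 + 2)  # none + kde x2 + sigmoid x2
  expect_warning(
    run_grid(ds_rec, thresholds = 10, modes = "none", classifiers = "lda",
             seed = 2, cv_folds = 50),
    "skipped")
})

test_that("the grid can tune per-feature bandwidths before scoring", {
  co <- withr::with_seed(9, {
    n <- 150
    y <- stats::runif(n) < 0.4
    x <- data.frame(info1 = stats::rnorm(n) + y, noise1 = stats::rnorm(n),
                    noise2 = stats::rnorm(n))
    df <- cbind(data.frame(patient_id = sprintf("S%03d", seq_len(n)),
                           sex = "male", age = 55L, fit_result = "negative",
                           max_polyp_mm = ifelse(y, 5L, 0L),
                           days_to_colonoscopy = 30L, flags = "",
                           stringsAsFactors = FALSE), x)
    class(df) <- c("cohort", "data.frame")
    df
  })
  sc <- feature_schema(c("info1", "noise1", "noise2"))
  g <- run_grid(co, thresholds = 0, modes = "kde", exponents = 2,
                classifiers = "logistic_regression", optimize_bw = TRUE,
                seed = 3, schema = sc)
  bw <- g$candidates[[1]]$spec$bandwidths
  expect_named(bw, c("info1", "noise1", "noise2"))
  expect_true(all(bw > 0))
})

test_that("rerunning the grid with the same seed reproduces the table", {
  rec <- generate_cohort(synthetic_spec(n_male = 150, n_female = 0, seed = 9))
  g1 <- run_grid(rec, thresholds = 0, modes = "sigmoid_kde", exponents = 2,
                 classifiers = "logistic_regression", seed = 4)
  g2 <- run_grid(rec, thresholds = 0, modes = "sigmoid_kde", exponents = 2,
                 classifiers = "logistic_regression", seed = 4)
  expect_equal(g1$table, g2$table)
})

test_that("select_best with k = 1 evaluates the CV-MCC argmax on test data", {
  rec <- generate_cohort(synthetic_spec(n_male = 200, n_female = 0, seed = 6))
  g <- run_grid(rec, thresholds = 0, modes = c("none", "kde"), exponents = 2,
                classifiers = c("logistic_regression", "lda"), seed = 3)
  sel1 <- select_best(g, k = 1)
  top_cv <- g$table$name[which.max(g$table$cv_mcc)]
  expect_equal(sel1$best$name, top_cv)
  # returned metrics are recomputable from the returned model's predictions
  sp <- g$splits[["0"]]
  sc <- predict_polyp_score(sel1$best, sp$test$x)
  rep <- metrics_report(sp$test$y, ifelse(sc >= 0.5, "yes", "no"), scores = sc)
  expect_equal(rep$mcc, sel1$metrics$mcc, tolerance = 1e-12)
  expect_equal(rep$auc, sel1$metrics$auc, tolerance = 1e-12)
  # k above the candidate count falls back to all with a warning
  expect_warning(select_best(g, k = 99), "exceeds")
})

test_that("a dominant planted model wins the final selection", {
  wins <- 0
  for (s in 1:10) {
    rec <- generate_cohort(synthetic_spec(n_male = 250, n_female = 0,
                                          delta = 1.2, seed = 500 + s))
    # only mode-none logistic sees the informative features; the noise-only
    # competitor fits a label-free feature subset
    prep <- prepare_cohort(rec)
    ds <- make_labels(prep$male, 0)
    sp <- split_train_test(ds, 0.25, seed = s)
    informative <- c("age", "bmi", "waist_cm", "hdl", "ggt", "drinking_freq")
    noise <- setdiff(colnames(ds$x), informative)[1:6]
    cands <- list(
      polypkde:::new_candidate("logistic_regression", transform_spec("none"),
                               0, informative, cv_mcc = 1, sex = "male",
                               seed = s),
      polypkde:::new_candidate("logistic_regression", transform_spec("none"),
                               0, noise, cv_mcc = 0.99, sex = "male", seed = s)
    )
    grid <- structure(list(table = NULL, candidates = cands,
                           splits = list(`0` = sp), schema = default_schema(),
                           seed = s), class = "grid_result")
    sel <- select_best(grid, k = 2)
    if (setequal(sel$best$features, informative)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("candidate naming follows the threshold/transform/classifier scheme", {
  expect_equal(
    polypkde:::candidate_name(0, "sigmoid_kde", 4, "gaussian_process"),
    "0 S-SKDE-4E-GP")
  expect_equal(polypkde:::candidate_name(8, "kde", 2, "logistic_regression"),
               "8 S-KDE-2E-LR")
  expect_equal(polypkde:::candidate_name(6, "none", NA, "lda"), "6 S-RAW-LDA")
})
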