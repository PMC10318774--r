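#' Stratified cross-validation fold assignment
#'
#' @param y factor labels.
#' @param k number of folds.
#' @param seed assignment seed.
#' @return integer vector of fold ids in 1..k.
#' @export
make_folds <- function(y, k = 5, seed = 1) {
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) < k) {
        stop("class '", cl, "' has fewer members (", length(idx),
             ") than folds (", k, ")")
      }
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Cross-validated MCC of a transform + classifier on training data
#'
#' Stratified k-fold CV in which the feature transform is re-fitted on each
#' fold's training part (positive class only), so no density information
#' leaks into the held-out fold. Predictions use the 0.5 polyp-score cut.
#'
#' @param train a `labeled_dataset`.
#' @param classifier classifier id.
#' @param spec a `transform_spec`.
#' @param features feature subset (default all).
#' @param cv_folds number of folds.
#' @param schema feature schema.
#' @param seed seed for folds and stochastic learners.
#' @param folds optional precomputed fold vector.
#' @return list with `mean`, `per_fold`, and `fold_predictions` (data.frame
#'   of fold, truth, score, prediction) for independent recomputation.
#' @export
cv_mcc <- function(train, classifier, spec, features = colnames(train$x),
                   cv_folds = 5, schema = default_schema(), seed = 1,
                   folds = NULL) {
  if (is.null(folds)) folds <- make_folds(train$y, cv_folds, seed)
  k <- max(folds)
  per_fold <- numeric(k)
  preds <- vector("list", k)
  for (fo in seq_len(k)) {
    tr_i <- folds != fo
    tr <- subset_dataset(train, which(tr_i))
    te <- subset_dataset(train, which(!tr_i))
    if (length(unique(tr$y)) < 2 || length(unique(te$y)) < 2) {
      stop("cross-validation fold with a single class; use fewer folds")
    }
    ft <- fit_transform(tr, spec, schema, features = features)
    cl <- fit_classifier(classifier, apply_transform(ft, tr$x), tr$y,
                         seed = seed)
    sc <- predict_polyp_score(cl, apply_transform(ft, te$x))
    pr <- ifelse(sc >= 0.5, "yes", "no")
    rep <- metrics_report(te$y, pr)
    per_fold[fo] <- rep$mcc
    preds[[fo]] <- data.frame(fold = fo, truth = as.character(te$y),
                              score = sc, prediction = pr)
  }
  list(mean = mean(per_fold), per_fold = per_fold,
       fold_predictions = do.call(rbind, preds))
}

candidate_name <- function(threshold_mm, mode, exponent, classifier) {
  tr <- switch(mode, none = "RAW",
               kde = sprintf("KDE-%dE", exponent),
               sigmoid_kde = sprintf("SKDE-%dE", exponent))
  sprintf("%d S-%s-%s", threshold_mm, tr, classifier_abbrev(classifier))
}

new_candidate <- function(classifier, spec, threshold_mm, features, cv_mcc,
                          sex = NA_character_, seed = 1) {
  cand <- list(
    classifier = classifier, spec = spec, threshold_mm = threshold_mm,
    features = features, cv_mcc = cv_mcc, sex = sex, seed = seed,
    name = candidate_name(threshold_mm, spec$mode,
                          if (is.null(spec$exponent)) NA else spec$exponent,
                          classifier),
    transform = NULL, fit = NULL
  )
  class(cand) <- "candidate_model"
  cand
}

#' Backward feature elimination by cross-validated MCC
#'
#' Starting from the full feature set, each feature's removal is trialled by
#' re-running cross-validation without it; the feature whose removal yields
#' the highest CV MCC (the feature most harmful, or least helpful, to
#' discrimination) is eliminated, iterating until `floor` features remain.
#' One candidate is recorded per iteration, so the path has
#' `p - floor + 1` strictly nested feature sets. Ties break by schema order.
#'
#' @param train a `labeled_dataset`.
#' @param classifier classifier id.
#' @param spec a `transform_spec`.
#' @param cv_folds folds.
#' @param floor minimum feature count (default 3).
#' @param schema feature schema.
#' @param seed seed (folds are fixed across the whole path).
#' @return list of `candidate_model`s, full set first.
#' @export
backward_eliminate <- function(train, classifier, spec, cv_folds = 5,
                               floor = 3, schema = default_schema(),
                               seed = 1) {
  features <- colnames(train$x)
  stopifnot(length(features) >= floor)
  folds <- make_folds(train$y, cv_folds, seed)
  path <- list()
  current <- features
  repeat {
    cm <- cv_mcc(train, classifier, spec, features = current,
                 cv_folds = cv_folds, schema = schema, seed = seed,
                 folds = folds)
    path[[length(path) + 1]] <- new_candidate(classifier, spec,
                                              train$threshold_mm, current,
                                              cm$mean, seed = seed)
    if (length(current) <= floor) break
    drop_scores <- vapply(current, function(f) {
      cv_mcc(train, classifier, spec, features = setdiff(current, f),
             cv_folds = cv_folds, schema = schema, seed = seed,
             folds = folds)$mean
    }, numeric(1))
    current <- setdiff(current, current[which.max(drop_scores)])
  }
  path
}

grid_cells <- function(modes, exponents) {
  cells <- list()
  for (m in modes) {
    if (m == "none") {
      cells[[length(cells) + 1]] <- list(mode = "none", exponent = NA_integer_)
    } else {
      for (e in exponents) {
        cells[[length(cells) + 1]] <- list(mode = m, exponent = e)
      }
    }
  }
  cells
}

#' Optimization grid over thresholds, transforms and classifiers
#'
#' For each polyp-size threshold the cohort is relabelled and split
#' (stratified, fixed seed) and missing values are median-imputed from the
#' training split; then every (transform mode, exponent, classifier) cell is
#' scored by cross-validated training MCC — with an optional backward
#' elimination path per cell, in which case a cell's row carries the best
#' CV MCC along its path. Combinations whose labelling leaves a class empty
#' are skipped with a warning.
#'
#' @param records eligible cohort records of one sex.
#' @param thresholds polyp-size thresholds (subset of 0, 6, 8, 10).
#' @param modes transform modes (subset of none, kde, sigmoid_kde).
#' @param exponents KDE exponents (subset of 1:4; ignored for mode none).
#' @param classifiers classifier ids.
#' @param eliminate run backward elimination per cell (slow) or score the
#'   full feature set only.
#' @param optimize_bw tune per-feature bandwidths coordinate-wise before
#'   scoring (slow); default uses Silverman's rule per feature.
#' @param test_fraction,cv_folds,seed split/CV controls.
#' @param schema feature schema.
#' @param floor elimination floor.
#' @return list of class `grid_result`: `table` (one row per cell),
#'   `candidates` (best candidate per cell), `splits` (per threshold).
#' @export
run_grid <- function(records, thresholds = c(0, 6, 8, 10),
                     modes = c("none", "kde", "sigmoid_kde"),
                     exponents = 1:4, classifiers = classifier_zoo(),
                     eliminate = FALSE, optimize_bw = FALSE,
                     test_fraction = 0.25, cv_folds = 5, seed = 1,
                     schema = default_schema(), floor = 3) {
  splits <- list()
  rows <- list(); cands <- list()
  sex <- if (length(unique(records$sex)) == 1) records$sex[1] else "mixed"
  for (thr in thresholds) {
    ds <- make_labels(records, thr, schema)
    if (min(table(ds$y)) < 2 * cv_folds) {
      warning("threshold ", thr, ": class too small, combination skipped")
      next
    }
    sp <- split_train_test(ds, test_fraction, seed)
    med <- impute_medians(sp$train$x)
    sp$train$x <- apply_imputation(sp$train$x, med)
    sp$test$x <- apply_imputation(sp$test$x, med)
    splits[[as.character(thr)]] <- sp
    for (cell in grid_cells(modes, exponents)) {
      spec <- if (cell$mode == "none") transform_spec("none") else
        transform_spec(cell$mode, cell$exponent)
      for (clf in classifiers) {
        if (isTRUE(optimize_bw) && cell$mode != "none") {
          bw <- vapply(colnames(sp$train$x), function(f) {
            as.numeric(optimize_bandwidth(sp$train, f, clf, spec,
                                          cv_folds = cv_folds,
                                          schema = schema, seed = seed))
          }, numeric(1))
          spec$bandwidths <- bw
        }
        if (eliminate) {
          path <- backward_eliminate(sp$train, clf, spec, cv_folds = cv_folds,
                                     floor = floor, schema = schema,
                                     seed = seed)
          best <- path[[which.max(vapply(path, `[[`, numeric(1), "cv_mcc"))]]
        } else {
          cm <- cv_mcc(sp$train, clf, spec, cv_folds = cv_folds,
                       schema = schema, seed = seed)
          best <- new_candidate(clf, spec, thr, colnames(sp$train$x),
                                cm$mean, sex = sex, seed = seed)
        }
        best$sex <- sex
        cands[[length(cands) + 1]] <- best
        rows[[length(rows) + 1]] <- data.frame(
          sex = sex, threshold_mm = thr, mode = cell$mode,
          exponent = cell$exponent, classifier = clf,
          n_features = length(best$features), cv_mcc = best$cv_mcc,
          name = best$name, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- list(table = do.call(rbind, rows), candidates = cands,
              splits = splits, schema = schema, seed = seed)
  class(out) <- "grid_result"
  out
}

#' Refit a candidate on its full training split
#'
#' @param cand a `candidate_model`.
#' @param train training `labeled_dataset`.
#' @param schema feature schema.
#' @return The candidate with fitted `transform` and `fit` slots.
#' @export
fit_candidate <- function(cand, train, schema = default_schema()) {
  tr_ds <- train
  tr_ds$x <- train$x[, cand$features, drop = FALSE]
  cand$transform <- fit_transform(tr_ds, cand$spec, schema,
                                  features = cand$features)
  cand$fit <- fit_classifier(cand$classifier,
                             apply_transform(cand$transform, tr_ds$x),
                             tr_ds$y, seed = cand$seed)
  cand
}

#' @export
predict_polyp_score.candidate_model <- function(object, x, ...) {
  if (is.null(object$fit)) stop("candidate model is not fitted; ",
                                "call fit_candidate() first")
  predict_polyp_score(object$fit, apply_transform(object$transform, x))
}

#' Evaluate a fitted candidate on a dataset
#'
#' @param cand fitted `candidate_model`.
#' @param dataset a `labeled_dataset`.
#' @return A `metrics_report` (0.5 score cut).
#' @export
evaluate_candidate <- function(cand, dataset) {
  sc <- predict_polyp_score(cand, dataset$x)
  metrics_report(dataset$y, ifelse(sc >= 0.5, "yes", "no"), scores = sc)
}

#' Select the best model from a grid by held-out MCC
#'
#' The top `k` candidates by cross-validated training MCC are refit on their
#' full training split and scored on the corresponding test split; the test
#' MCC argmax wins. Ties break by higher CV MCC, then by classifier order in
#' the zoo.
#'
#' @param grid a `grid_result` from [run_grid()].
#' @param k how many finalists to evaluate on test data (default 6).
#' @return list with `best` (fitted candidate), `metrics` (its test
#'   `metrics_report`), and `leaderboard` (one row per finalist).
#' @export
select_best <- function(grid, k = 6) {
  cands <- grid$candidates
  if (k > length(cands)) {
    warning("k exceeds the number of candidates; using all ", length(cands))
    k <- length(cands)
  }
  cv <- vapply(cands, `[[`, numeric(1), "cv_mcc")
  clf_rank <- match(vapply(cands, `[[`, character(1), "classifier"),
                    classifier_zoo())
  top <- order(-cv, clf_rank)[seq_len(k)]
  rows <- list(); fitted <- list()
  for (i in top) {
    cand <- cands[[i]]
    sp <- grid$splits[[as.character(cand$threshold_mm)]]
    cand <- fit_candidate(cand, sp$train, grid$schema)
    rep <- evaluate_candidate(cand, sp$test)
    fitted[[length(fitted) + 1]] <- cand
    rows[[length(rows) + 1]] <- data.frame(
      name = cand$name, sex = cand$sex, threshold_mm = cand$threshold_mm,
      mode = cand$spec$mode,
      exponent = if (is.null(cand$spec$exponent)) NA_integer_ else
        cand$spec$exponent,
      classifier = cand$classifier, n_features = length(cand$features),
      cv_mcc = cand$cv_mcc, test_sensitivity = rep$sensitivity,
      test_specificity = rep$specificity, test_accuracy = rep$accuracy,
      test_auc = rep$auc, test_mcc = rep$mcc, stringsAsFactors = FALSE
    )
  }
  lb <- do.call(rbind, rows)
  best_i <- order(-lb$test_mcc, -lb$cv_mcc,
                  match(lb$classifier, classifier_zoo()))[1]
  best <- fitted[[best_i]]
  sp <- grid$splits[[as.character(best$threshold_mm)]]
  list(best = best, metrics = evaluate_candidate(best, sp$test),
       leaderboard = lb)
}
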