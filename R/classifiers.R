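#' The classifier zoo
#'
#' Identifiers of the fixed-hyperparameter classifiers the optimization grid
#' may draw from. Hyperparameters are fixed, widely used defaults (recorded
#' in the fitting code); none of the classifiers standardizes its inputs
#' internally — putting features on a common probability-like scale is the
#' transform's job, and the mode-none baseline is deliberately exposed to
#' the raw measurement scales.
#'
#' @return character vector of classifier ids, in canonical order.
#' @export
classifier_zoo <- function() {
  c("adaboost", "bernoulli_nb", "gaussian_process", "gradient_boost", "lda",
    "linear_svc", "logistic_regression", "mlp", "ridge", "svc")
}

classifier_abbrev <- function(id) {
  c(adaboost = "AB", bernoulli_nb = "BNB", gaussian_process = "GP",
    gradient_boost = "GB", lda = "LDA", linear_svc = "LSVC",
    logistic_regression = "LR", mlp = "MLP", ridge = "RIDGE",
    svc = "SVC")[[id]]
}

drop_constant_cols <- function(x) {
  keep <- vapply(x, function(v) length(unique(v)) > 1, logical(1))
  names(keep)[keep]
}

# Discrete AdaBoost.M1 over decision stumps (rpart, depth 1). No boosting
# package ships stumps with observation weights in this form, so the loop
# is written out; the score is the weighted vote fraction for "yes".
fit_adaboost <- function(x, y, n_rounds = 50) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- cbind(x, .y = y)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    st <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                       control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                      minsplit = 2,
                                                      xval = 0))
    pred <- stats::predict(st, df, type = "class")
    err <- sum(w * (pred != y))
    if (err <= 1e-10) { stumps[[m]] <- st; alphas[m] <- 10; break }
    if (err >= 0.5) break
    a <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- st; alphas[m] <- a
    w <- w * exp(a * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  if (length(stumps) == 0) {  # unlearnable: constant majority vote
    stumps <- list(NULL); alphas <- 1
  }
  list(stumps = stumps, alphas = alphas,
       majority = names(which.max(table(y))))
}

predict_adaboost <- function(fit, x) {
  votes <- matrix(0, nrow(x), length(fit$stumps))
  for (m in seq_along(fit$stumps)) {
    st <- fit$stumps[[m]]
    pred <- if (is.null(st)) rep(fit$majority, nrow(x)) else
      as.character(stats::predict(st, x, type = "class"))
    votes[, m] <- as.numeric(pred == "yes")
  }
  as.numeric(votes %*% fit$alphas) / sum(fit$alphas)
}

#' Fit one classifier of the zoo
#'
#' Trains a classifier on a design matrix of (possibly transformed) features
#' against binary polyp labels. Hyperparameters are fixed: ridge-penalized
#' logistic regression and ridge least squares at `lambda = 1/n`; SVMs at
#' `cost = 1` with an RBF width of `1 / (p * var(X))` for the radial kernel;
#' a Gaussian process with an RBF kernel and quantile-based width; a
#' single-hidden-layer perceptron (5 units, weight decay 0.1); gradient
#' boosting with 100 depth-3 trees at learning rate 0.1; AdaBoost over 50
#' stumps; Bernoulli naive Bayes on features binarized at their training
#' medians. Constant columns are dropped internally; nothing is
#' standardized. Every fit is reproducible for a fixed seed.
#'
#' @param id a [classifier_zoo()] identifier.
#' @param x data.frame of numeric features (training split).
#' @param y factor with levels `no`, `yes`.
#' @param seed integer seed for stochastic learners.
#' @return A `polyp_classifier` object usable with [predict_polyp_score()].
#' @export
fit_classifier <- function(id, x, y, seed = 1) {
  id <- match.arg(id, classifier_zoo())
  stopifnot(is.factor(y), identical(levels(y), c("no", "yes")))
  cols <- drop_constant_cols(x)
  obj <- list(id = id, cols = cols, levels = levels(y), score_type = "prob")
  if (length(cols) == 0) {
    obj$fit <- NULL
    obj$const_score <- mean(y == "yes")
    class(obj) <- "polyp_classifier"
    return(obj)
  }
  xs <- x[, cols, drop = FALSE]
  xm <- as.matrix(xs)
  n <- nrow(xm)
  withr::with_seed(seed, switch(
    id,
    logistic_regression = {
      xr <- if (ncol(xm) == 1) cbind(xm, .pad = 0) else xm
      obj$fit <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                                lambda = 1 / n, standardize = FALSE)
      obj$pad <- ncol(xm) == 1
    },
    lda = {
      # lda needs nonzero pooled within-class variance per variable
      gmeans <- apply(xm, 2, function(v) tapply(v, y, mean))
      centered <- xm - gmeans[as.integer(y), , drop = FALSE]
      ok <- sqrt(diag(stats::var(centered))) >= 1e-3
      if (!any(ok)) {
        obj$cols <- character(0)
        obj$const_score <- mean(y == "yes")
      } else {
        obj$cols <- cols <- cols[ok]
        xm <- xm[, ok, drop = FALSE]
        obj$fit <- MASS::lda(xm, grouping = y)
      }
    },
    ridge = {
      xr <- if (ncol(xm) == 1) cbind(xm, .pad = 0) else xm
      obj$fit <- glmnet::glmnet(xr, as.numeric(y == "yes") * 2 - 1,
                                family = "gaussian", alpha = 0,
                                lambda = 1 / n, standardize = FALSE)
      obj$pad <- ncol(xm) == 1
      obj$score_type <- "decision"
    },
    linear_svc = {
      obj$fit <- e1071::svm(xm, y, kernel = "linear", cost = 1, scale = FALSE)
      obj$score_type <- "decision"
    },
    svc = {
      obj$fit <- e1071::svm(xm, y, kernel = "radial", cost = 1, scale = FALSE,
                            gamma = 1 / (ncol(xm) * max(stats::var(c(xm)),
                                                        1e-12)))
      obj$score_type <- "decision"
    },
    gaussian_process = {
      log <- utils::capture.output(
        obj$fit <- kernlab::gausspr(xm, y, type = "classification",
                                    kernel = "rbfdot", scaled = FALSE))
    },
    mlp = {
      obj$fit <- nnet::nnet(xm, as.numeric(y == "yes"), size = 5, decay = 0.1,
                            maxit = 200, trace = FALSE, entropy = TRUE)
    },
    gradient_boost = {
      obj$fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.1,
                      max_depth = 3, nthread = 1),
        data = xgboost::xgb.DMatrix(xm, label = as.numeric(y == "yes"),
                                    nthread = 1),
        nrounds = 100, verbose = 0)
    },
    adaboost = {
      obj$fit <- fit_adaboost(xs, y)
    },
    bernoulli_nb = {
      cuts <- vapply(xs, stats::median, numeric(1))
      xb <- as.data.frame(lapply(seq_along(xs), function(j) {
        factor(xs[[j]] > cuts[j], levels = c(FALSE, TRUE))
      }))
      names(xb) <- cols
      obj$cuts <- cuts
      obj$fit <- e1071::naiveBayes(xb, y, laplace = 1)
    }
  ))
  if (obj$score_type == "decision") {
    raw <- raw_score(obj, x)
    obj$score_range <- range(raw)
  }
  class(obj) <- "polyp_classifier"
  obj
}

raw_score <- function(obj, x) {
  if (length(obj$cols) == 0) return(rep(obj$const_score, nrow(x)))
  xs <- x[, obj$cols, drop = FALSE]
  xm <- as.matrix(xs)
  switch(
    obj$id,
    logistic_regression = ,
    ridge = {
      xr <- if (isTRUE(obj$pad)) cbind(xm, .pad = 0) else xm
      as.numeric(stats::predict(obj$fit, xr, type = "response"))
    },
    lda = as.numeric(stats::predict(obj$fit, xm)$posterior[, "yes"]),
    linear_svc = ,
    svc = {
      dv <- attr(stats::predict(obj$fit, xm, decision.values = TRUE),
                 "decision.values")
      d <- as.numeric(dv)
      # e1071 orients the decision value toward the first class of the
      # column label "A/B"; flip so higher means "yes"
      if (grepl("^no/", colnames(dv)[1])) -d else d
    },
    gaussian_process = as.numeric(
      kernlab::predict(obj$fit, xm, type = "probabilities")[, "yes"]),
    mlp = as.numeric(stats::predict(obj$fit, xm)),
    gradient_boost = as.numeric(stats::predict(
      obj$fit, xgboost::xgb.DMatrix(xm, nthread = 1))),
    adaboost = predict_adaboost(obj$fit, xs),
    bernoulli_nb = {
      xb <- as.data.frame(lapply(seq_along(obj$cols), function(j) {
        factor(xs[[j]] > obj$cuts[j], levels = c(FALSE, TRUE))
      }))
      names(xb) <- obj$cols
      as.numeric(stats::predict(obj$fit, xb, type = "raw")[, "yes"])
    }
  )
}

#' Polyp score of a fitted classifier
#'
#' Returns the class-"yes" probability when the classifier provides one;
#' otherwise the decision function is min-max scaled using the training-set
#' score extremes and clamped to [0, 1]. Scores are deterministic for a
#' fixed model and input.
#'
#' @param object a `polyp_classifier` or `candidate_model`.
#' @param x data.frame of features (same space the model was fitted in:
#'   transformed features for a `polyp_classifier` inside a pipeline, raw
#'   features for a `candidate_model`).
#' @param ... unused.
#' @return numeric scores in [0, 1].
#' @export
predict_polyp_score <- function(object, x, ...) UseMethod("predict_polyp_score")

#' @export
predict_polyp_score.polyp_classifier <- function(object, x, ...) {
  s <- raw_score(object, x)
  if (object$score_type == "decision") {
    rg <- object$score_range
    span <- diff(rg)
    s <- if (span <= 0) rep(0.5, length(s)) else (s - rg[1]) / span
  }
  pmin(pmax(s, 0), 1)
}
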