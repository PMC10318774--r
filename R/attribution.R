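shap_value_fn <- function(model, background) {
  # v(S) for an instance x: mean model score over background rows with the
  # features in S replaced by x's values
  function(x_row, masks) {
    b <- nrow(background)
    reps <- background[rep(seq_len(b), nrow(masks)), , drop = FALSE]
    for (j in seq_len(ncol(masks))) {
      rows <- rep(masks[, j], each = b)
      reps[rows, j] <- x_row[[j]]
    }
    sc <- predict_polyp_score(model, reps)
    colMeans(matrix(sc, nrow = b))
  }
}

shapley_exact <- function(model, background, x_row, p) {
  n_sub <- 2^p
  masks <- matrix(FALSE, n_sub, p)
  for (j in seq_len(p)) masks[, j] <- bitwAnd(seq_len(n_sub) - 1L,
                                              bitwShiftL(1L, j - 1L)) > 0
  v <- shap_value_fn(model, background)(x_row, masks)
  sizes <- rowSums(masks)
  lf <- lgamma(seq_len(p + 1))  # lgamma(k+1) = log(k!)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    without <- which(!masks[, j])
    with_j <- without + 2^(j - 1)
    s <- sizes[without]
    w <- exp(lf[s + 1] + lf[p - s] - lf[p + 1])  # |S|! (p-|S|-1)! / p!
    phi[j] <- sum(w * (v[with_j] - v[without]))
  }
  phi
}

shapley_sampled <- function(model, background, x_row, p, n_samples) {
  n_perm <- max(1L, floor(n_samples / p))
  b_idx <- sample.int(nrow(background), n_perm, replace = TRUE)
  # build all hybrid rows for all permutations, one batched predict
  hybrids <- vector("list", n_perm)
  orders <- vector("list", n_perm)
  for (s in seq_len(n_perm)) {
    perm <- sample.int(p)
    orders[[s]] <- perm
    z <- background[rep(b_idx[s], p + 1), , drop = FALSE]
    for (step in seq_len(p)) {
      fixed <- perm[seq_len(step)]
      z[step + 1, fixed] <- x_row[fixed]
    }
    hybrids[[s]] <- z
  }
  sc <- predict_polyp_score(model, do.call(rbind, hybrids))
  scm <- matrix(sc, nrow = p + 1)
  phi <- numeric(p)
  for (s in seq_len(n_perm)) {
    contrib <- diff(scm[, s])
    phi[orders[[s]]] <- phi[orders[[s]]] + contrib
  }
  phi / n_perm
}

#' Shapley-value feature attribution
#'
#' Estimates per-record, per-feature Shapley values of the polyp score with
#' respect to a background sample: exact enumeration over all coalitions
#' when the model has at most 12 features, otherwise permutation sampling.
#' Feature importance is the mean absolute attribution over the explained
#' records. Attributions satisfy additivity: base value plus the row sum
#' equals the model's score (exactly for exact mode, within Monte-Carlo
#' noise bounded by construction — each sampled permutation telescopes).
#'
#' @param model fitted model exposing [predict_polyp_score()] (a
#'   `candidate_model` or `polyp_classifier`).
#' @param background data.frame of background feature rows (capped at 100,
#'   sampled reproducibly).
#' @param explain data.frame of rows to explain.
#' @param n_samples total marginal-contribution samples per record for the
#'   sampled estimator (must be >= 2 * p).
#' @param seed RNG seed.
#' @param exact force/forbid exact enumeration (default: automatic, p <= 12).
#' @return list of class `attribution_report`: `importance` (data.frame,
#'   ranked), `attributions` (records x features), `base_value`, `scores`.
#' @export
shapley_importance <- function(model, background, explain, n_samples = 256,
                               seed = 1, exact = NULL) {
  stopifnot(nrow(background) > 0)
  features <- if (inherits(model, "candidate_model")) model$features else
    colnames(background)
  background <- background[, features, drop = FALSE]
  explain <- explain[, features, drop = FALSE]
  p <- length(features)
  if (is.null(exact)) exact <- p <= 12
  if (!exact && n_samples < 2 * p) {
    stop("sampling budget too small: n_samples must be >= 2 * n_features")
  }
  withr::with_seed(seed, {
    if (nrow(background) > 100) {
      background <- background[sample.int(nrow(background), 100), ,
                               drop = FALSE]
    }
    base_value <- mean(predict_polyp_score(model, background))
    phi <- t(vapply(seq_len(nrow(explain)), function(i) {
      x_row <- explain[i, , drop = FALSE]
      if (exact) shapley_exact(model, background, x_row, p)
      else shapley_sampled(model, background, x_row, p, n_samples)
    }, numeric(p)))
  })
  colnames(phi) <- features
  scores <- predict_polyp_score(model, explain)
  imp <- data.frame(feature = features,
                    importance = colMeans(abs(phi)),
                    mean_attribution = colMeans(phi))
  imp <- imp[order(-imp$importance), ]
  rownames(imp) <- NULL
  out <- list(importance = imp, attributions = phi, base_value = base_value,
              scores = scores, exact = exact)
  class(out) <- "attribution_report"
  out
}

#' Write an attribution report to JSON
#' @param report an `attribution_report`.
#' @param path file path.
#' @export
write_attribution_json <- function(report, path) {
  out <- unclass(report)
  out$attributions <- as.data.frame(out$attributions)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-patient biomarker risk report
#'
#' For one patient under a sigmoid-KDE model: the polyp score, every
#' feature's transformed (probability-like) value with a flag when it is
#' near saturation (>= `flag_threshold`, i.e. the patient sits in the
#' risk-saturated range of that biomarker), and the top contributing
#' features by Shapley value. Intended as counselling output: flagged
#' features are the measurements where lifestyle or clinical follow-up
#' could plausibly move the patient off the saturated range.
#'
#' @param model fitted `candidate_model` with transform mode `sigmoid_kde`.
#' @param record one cohort record (data.frame row with feature columns).
#' @param background background rows for the Shapley baseline.
#' @param flag_threshold near-saturation flag cut (default 0.9).
#' @param top_m how many top contributors to list.
#' @param n_samples,seed Shapley controls.
#' @return list of class `patient_risk_report`.
#' @export
patient_risk_report <- function(model, record, background,
                                flag_threshold = 0.9, top_m = 3,
                                n_samples = 256, seed = 1) {
  if (is.null(model$spec) || model$spec$mode != "sigmoid_kde") {
    stop("patient_risk_report requires a model with a sigmoid-KDE ",
         "transform: per-feature saturation flags are only meaningful for ",
         "monotone risk curves")
  }
  x <- record[, model$features, drop = FALSE]
  tx <- apply_transform(model$transform, x)
  tvals <- unlist(tx[1, , drop = TRUE])
  attr_rep <- shapley_importance(model, background, x, n_samples = n_samples,
                                 seed = seed)
  phi <- attr_rep$attributions[1, ]
  top <- names(sort(abs(phi), decreasing = TRUE))[seq_len(min(top_m,
                                                              length(phi)))]
  out <- list(
    polyp_score = predict_polyp_score(model, x),
    transformed = tvals,
    flagged = names(tvals)[tvals >= flag_threshold],
    flag_threshold = flag_threshold,
    top_contributors = data.frame(feature = top,
                                  attribution = unname(phi[top])),
    base_value = attr_rep$base_value
  )
  class(out) <- "patient_risk_report"
  out
}

#' @export
print.patient_risk_report <- function(x, ...) {
  cat(sprintf("polyp score: %.3f (baseline %.3f)\n",
              x$polyp_score, x$base_value))
  cat(sprintf("features at/near risk saturation (>= %.2f): %s\n",
              x$flag_threshold,
              if (length(x$flagged) == 0) "none" else
                paste(x$flagged, collapse = ", ")))
  cat("top contributors:\n")
  for (i in seq_len(nrow(x$top_contributors))) {
    cat(sprintf("  %-18s %+0.4f\n", x$top_contributors$feature[i],
                x$top_contributors$attribution[i]))
  }
  invisible(x)
}
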