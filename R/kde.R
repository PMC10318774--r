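#' Silverman's rule-of-thumb bandwidth
#'
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)`, with a guard for degenerate
#' samples (zero spread returns 1 so downstream transforms stay defined).
#'
#' @param values numeric sample.
#' @return bandwidth > 0.
#' @export
silverman_bw <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) return(1)
  s <- stats::sd(values)
  iqr <- stats::IQR(values) / 1.34
  spread <- min(c(s, iqr)[c(s, iqr) > 0], Inf)
  if (!is.finite(spread)) return(1)
  0.9 * spread * n^(-1 / 5)
}

#' Gaussian kernel density on an even grid
#'
#' Direct kernel sum `(1/nh) * sum(phi((x - x_i)/h))` evaluated on an even
#' grid spanning `[min - 3h, max + 3h]`. The sum is computed exactly (no
#' binning or FFT approximation) because the transform's values at grid
#' points are the package's core primitive.
#'
#' @param values numeric sample (>= 2 values).
#' @param h bandwidth > 0.
#' @param grid_size number of grid points.
#' @return List with `grid` and `density`.
#' @export
fit_density <- function(values, h, grid_size = 512) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("density fit needs at least 2 values")
  if (!is.numeric(h) || h <= 0) stop("bandwidth h must be positive")
  grid <- seq(min(values) - 3 * h, max(values) + 3 * h, length.out = grid_size)
  dens <- rowMeans(stats::dnorm(outer(grid, values, "-") / h)) / h
  list(grid = grid, density = dens)
}

#' Normalize a density to unit maximum and apply an integer exponent
#'
#' The raw KDE is rescaled so its maximum is exactly 1, then raised to an
#' integer exponent in 1..4; exponentiation sharpens the contrast between
#' the modal region and the tails while fixing the maximum at 1.
#'
#' @param raw list from [fit_density()].
#' @param e exponent in `{1, 2, 3, 4}`.
#' @param feature feature name carried in the model.
#' @param h bandwidth used for the fit (metadata).
#' @return A `density_model`: grid, transformed values in (0, 1],
#'   exponent, mode `"kde"`, and the argmax grid point.
#' @export
normalize_and_power <- function(raw, e, feature = "", h = NA_real_) {
  if (!e %in% 1:4) stop("exponent must be one of 1, 2, 3, 4")
  mx <- max(raw$density)
  if (!is.finite(mx) || mx <= 0) stop("cannot normalize an all-zero density")
  base <- raw$density / mx
  dm <- list(
    feature = feature,
    grid = raw$grid,
    base = base,               # normalized, pre-exponent
    values = base^e,
    h = h,
    exponent = as.integer(e),
    mode = "kde",
    direction = NA_character_,
    argmax = raw$grid[which.max(base)]
  )
  class(dm) <- "density_model"
  dm
}

#' Clamp a KDE into a monotone sigmoid-like risk curve
#'
#' All grid values on one side of the density maximum are set to 1 —
#' `direction = "higher"` saturates risk for values at or above the argmax,
#' `direction = "lower"` for values at or below it — and the remaining limb
#' is forced monotone by a running maximum toward the argmax (identity for
#' a unimodal KDE). The exponent is applied after clamping; clamped values
#' are 1 and unaffected.
#'
#' @param dm a `density_model` with mode `"kde"`.
#' @param direction `"higher"` or `"lower"`.
#' @return A `density_model` with mode `"sigmoid_kde"`, monotone on the grid.
#' @export
sigmoidize <- function(dm, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (dm$mode != "kde") stop("sigmoidize expects a plain-KDE density model")
  base <- dm$base
  k <- which.max(base)
  n <- length(base)
  if (direction == "higher") {
    base[k:n] <- 1
    if (k > 1) base[1:(k - 1)] <- cummax(base[1:(k - 1)])
  } else {
    base[1:k] <- 1
    if (k < n) base[k:n] <- rev(cummax(rev(base[k:n])))
  }
  dm$base <- base
  dm$values <- base^dm$exponent
  dm$mode <- "sigmoid_kde"
  dm$direction <- direction
  dm
}

#' Evaluate a density model at new points
#'
#' Linear interpolation on the stored grid; points outside the grid clamp
#' to the nearest end value. Output lies in (0, 1].
#'
#' @param dm a `density_model`.
#' @param x numeric values.
#' @return numeric vector of transformed values.
#' @export
transform_value <- function(dm, x) {
  stats::approx(dm$grid, dm$values, xout = x, rule = 2)$y
}

#' Serialize / restore a density model as JSON
#'
#' @param dm a `density_model`.
#' @param path file path.
#' @export
write_density_model <- function(dm, path) {
  jsonlite::write_json(unclass(dm), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_density_model
#' @export
read_density_model <- function(path) {
  dm <- jsonlite::fromJSON(path)
  dm$exponent <- as.integer(dm$exponent)
  class(dm) <- "density_model"
  dm
}

#' Specification of a feature transform
#'
#' @param mode `"none"`, `"kde"` or `"sigmoid_kde"`.
#' @param exponent integer 1..4 (ignored for mode `"none"`).
#' @param bandwidths optional named per-feature bandwidths; features not
#'   named fall back to Silverman's rule on the fitting sample.
#' @param directions optional named per-feature directions overriding the
#'   schema (`sigmoid_kde` only).
#' @return A list of class `transform_spec`.
#' @export
transform_spec <- function(mode = c("none", "kde", "sigmoid_kde"),
                           exponent = 1, bandwidths = NULL,
                           directions = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") {
    ts <- list(mode = "none")
  } else {
    if (!exponent %in% 1:4) stop("exponent must be one of 1, 2, 3, 4")
    ts <- list(mode = mode, exponent = as.integer(exponent),
               bandwidths = bandwidths, directions = directions)
  }
  class(ts) <- "transform_spec"
  ts
}

resolve_direction <- function(feature, spec, schema, x, y) {
  if (!is.null(spec$directions) && feature %in% names(spec$directions)) {
    return(spec$directions[[feature]])
  }
  dir <- schema$kde_direction[match(feature, schema$name)]
  if (is.na(dir)) dir <- "auto"
  if (dir == "auto") {
    med_yes <- stats::median(x[y == "yes"], na.rm = TRUE)
    med_no <- stats::median(x[y == "no"], na.rm = TRUE)
    dir <- if (isTRUE(med_yes >= med_no)) "higher" else "lower"
  }
  dir
}

#' Fit per-feature density transforms on the polyp-positive class
#'
#' For each feature, a KDE is fitted on the `"yes"` (polyp) class of the
#' training data only, normalized to unit maximum, exponentiated, and — in
#' sigmoid mode — clamped to 1 on the feature's risk-saturating side
#' (schema direction, or inferred from training class medians when
#' `"auto"`). Mode `"none"` returns an identity transform.
#'
#' @param train a `labeled_dataset` (training split).
#' @param spec a [transform_spec()].
#' @param schema a `feature_schema`.
#' @param features features to transform (default: all columns of `train$x`).
#' @param grid_size KDE grid resolution.
#' @return A `feature_transform`: list of `density_model`s keyed by feature.
#' @export
fit_transform <- function(train, spec, schema = default_schema(),
                          features = colnames(train$x), grid_size = 512) {
  stopifnot(inherits(spec, "transform_spec"))
  models <- NULL
  if (spec$mode != "none") {
    models <- lapply(features, function(f) {
      v <- train$x[[f]][train$y == "yes"]
      v <- v[!is.na(v)]
      h <- if (!is.null(spec$bandwidths) && f %in% names(spec$bandwidths)) {
        spec$bandwidths[[f]]
      } else {
        silverman_bw(v)
      }
      if (length(unique(v)) < 2) {
        # degenerate positive-class feature: flat unit transform
        dm <- list(feature = f, grid = range(train$x[[f]], na.rm = TRUE),
                   base = c(1, 1), values = c(1, 1), h = h,
                   exponent = if (is.null(spec$exponent)) 1L else spec$exponent,
                   mode = spec$mode, direction = NA_character_,
                   argmax = v[1])
        class(dm) <- "density_model"
        return(dm)
      }
      dm <- normalize_and_power(fit_density(v, h, grid_size), spec$exponent,
                                feature = f, h = h)
      if (spec$mode == "sigmoid_kde") {
        dm <- sigmoidize(dm, resolve_direction(f, spec, schema,
                                               train$x[[f]], train$y))
      }
      dm
    })
    names(models) <- features
  }
  tr <- list(mode = spec$mode, spec = spec, features = features,
             models = models)
  class(tr) <- "feature_transform"
  tr
}

#' Apply a fitted feature transform to a design matrix
#'
#' @param tr a `feature_transform` from [fit_transform()].
#' @param x design data.frame containing the transform's features.
#' @return data.frame of the transform's features, transformed (identity
#'   for mode `"none"`).
#' @export
apply_transform <- function(tr, x) {
  out <- x[, tr$features, drop = FALSE]
  if (tr$mode == "none") return(out)
  for (f in tr$features) out[[f]] <- transform_value(tr$models[[f]], x[[f]])
  out
}

#' Coordinate-wise bandwidth optimization by cross-validated MCC
#'
#' For one feature, each candidate bandwidth in `h_grid` is substituted into
#' the transform (other features keep their current bandwidths), the full
#' model is re-fitted under stratified cross-validation, and the bandwidth
#' maximizing mean CV Matthews correlation is returned; ties break toward
#' the smallest bandwidth. A zero-variance feature is flagged and gets the
#' Silverman default.
#'
#' @param train a `labeled_dataset`.
#' @param feature feature name to tune.
#' @param classifier a classifier id (see [classifier_zoo()]).
#' @param spec a `transform_spec` (mode `"kde"` or `"sigmoid_kde"`).
#' @param cv_folds number of stratified folds.
#' @param h_grid candidate bandwidths; default Silverman x {1/4, 1/2, 1, 2, 4}.
#' @param schema feature schema.
#' @param seed fold-assignment seed.
#' @return Selected bandwidth, with attribute `"cv_mcc"` (and `"flagged"`
#'   for degenerate features).
#' @export
optimize_bandwidth <- function(train, feature, classifier, spec,
                               cv_folds = 5, h_grid = NULL,
                               schema = default_schema(), seed = 1) {
  stopifnot(feature %in% colnames(train$x))
  v <- train$x[[feature]][train$y == "yes"]
  v <- v[!is.na(v)]
  h0 <- silverman_bw(v)
  if (stats::var(v) == 0 || length(v) < 2) {
    out <- h0
    attr(out, "flagged") <- TRUE
    return(out)
  }
  if (is.null(h_grid)) h_grid <- h0 * c(0.25, 0.5, 1, 2, 4)
  if (length(h_grid) == 0) stop("h_grid must be non-empty")
  h_grid <- sort(h_grid)
  scores <- vapply(h_grid, function(h) {
    sp <- spec
    bw <- if (is.null(sp$bandwidths)) numeric(0) else sp$bandwidths
    bw[feature] <- h
    sp$bandwidths <- bw
    cv_mcc(train, classifier, sp, cv_folds = cv_folds, schema = schema,
           seed = seed)$mean
  }, numeric(1))
  best <- h_grid[which.max(scores)]  # which.max takes the first (smallest h)
  attr(best, "cv_mcc") <- max(scores)
  best
}
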