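#' Matthews correlation coefficient from confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' whenever a marginal of the confusion matrix is zero.
#'
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @return value in [-1, 1].
#' @export
mcc <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("confusion counts must be >= 0")
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  if (tp + tn + fp + fn == 0) stop("confusion counts sum to zero")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' ROC area and curve by the rank (Mann-Whitney) construction
#'
#' AUC equals the Mann-Whitney U statistic normalized by `n1 * n0`; tied
#' scores contribute 1/2. Curve points are returned at every distinct score
#' cut.
#'
#' @param labels factor/character/logical; `"yes"`/`TRUE`/1 is the positive
#'   class.
#' @param scores numeric scores, higher = more positive.
#' @return list with `auc` and `curve` (data.frame of fpr, tpr, threshold).
#' @export
roc_auc <- function(labels, scores) {
  pos <- labels %in% c("yes", TRUE, 1)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tps <- cumsum(pos[ord]); fps <- cumsum(!pos[ord])
  last <- !duplicated(scores[ord], fromLast = TRUE)  # one point per cut
  curve <- data.frame(
    fpr = c(0, fps[last] / n0),
    tpr = c(0, tps[last] / n1),
    threshold = c(Inf, scores[ord][last])
  )
  list(auc = auc, curve = curve)
}

#' Confusion-matrix metrics report
#'
#' Confusion counts and derived sensitivity, specificity, accuracy, MCC,
#' optional AUC, and the confusion matrix normalized per true-class row.
#'
#' @param labels true labels (`"yes"` positive).
#' @param predictions predicted labels (`"yes"` positive).
#' @param scores optional numeric scores for AUC.
#' @return A list of class `metrics_report`.
#' @export
metrics_report <- function(labels, predictions, scores = NULL) {
  lab <- labels %in% c("yes", TRUE, 1)
  pred <- predictions %in% c("yes", TRUE, 1)
  tp <- sum(lab & pred); tn <- sum(!lab & !pred)
  fp <- sum(!lab & pred); fn <- sum(lab & !pred)
  cm <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
               dimnames = list(true = c("no", "yes"),
                               predicted = c("no", "yes")))
  rs <- rowSums(cm)
  norm_cm <- sweep(cm, 1, ifelse(rs == 0, 1, rs), "/")
  rep <- list(
    tp = tp, tn = tn, fp = fp, fn = fn, n = tp + tn + fp + fn,
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    auc = if (is.null(scores)) NA_real_ else roc_auc(labels, scores)$auc,
    mcc = mcc(tp, tn, fp, fn),
    confusion_normalized = norm_cm
  )
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "n=%d  TP=%d TN=%d FP=%d FN=%d\nsens=%.3f spec=%.3f acc=%.3f auc=%s mcc=%.3f\n",
    x$n, x$tp, x$tn, x$fp, x$fn, x$sensitivity, x$specificity, x$accuracy,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)), x$mcc))
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param rep a `metrics_report`.
#' @param path file path.
#' @export
write_metrics_json <- function(rep, path) {
  out <- unclass(rep)
  out$confusion_normalized <- as.data.frame(out$confusion_normalized)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' FIT screening baseline
#'
#' Treats a positive fecal immunochemical test as the predicted `"yes"` and
#' scores it against the polyp labels at a size threshold. Records with a
#' missing FIT are excluded (count attached as attribute `"n_missing_fit"`).
#'
#' @param records a cohort `data.frame`.
#' @param threshold_mm polyp-size threshold.
#' @param schema feature schema (for label construction).
#' @return A `metrics_report`.
#' @export
fit_baseline_metrics <- function(records, threshold_mm,
                                 schema = default_schema()) {
  known <- records$fit_result %in% c("positive", "negative")
  rec <- records[known, , drop = FALSE]
  ds <- make_labels(rec, threshold_mm, schema)
  rep <- metrics_report(ds$y, ifelse(rec$fit_result == "positive",
                                     "yes", "no"))
  attr(rep, "n_missing_fit") <- sum(!known)
  rep
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square p-value on
#' `(groups - 1)` degrees of freedom, via `stats::kruskal.test`.
#'
#' @param values numeric vector.
#' @param groups grouping vector (>= 2 non-empty groups).
#' @return list with `H` and `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2 || any(table(groups) == 0)) {
    stop("kruskal_wallis needs >= 2 non-empty groups")
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Per-feature Kruskal-Wallis screening table
#'
#' Screens every feature against the polyp label, reporting raw p-values as
#' well as a Benjamini-Hochberg column (emitted for reference, not used for
#' selection).
#'
#' @param dataset a `labeled_dataset`.
#' @return data.frame with feature, H, p, p_bh.
#' @export
kruskal_screen <- function(dataset) {
  res <- lapply(colnames(dataset$x), function(f) {
    ok <- !is.na(dataset$x[[f]])
    kw <- kruskal_wallis(dataset$x[[f]][ok], dataset$y[ok])
    data.frame(feature = f, H = kw$H, p = kw$p)
  })
  out <- do.call(rbind, res)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Polyp-score distribution summaries by prediction outcome
#'
#' For each confusion cell (TP/TN/FP/FN) and each true class, reports the
#' count, quartiles, and a unit-maximum score KDE (for violin/density
#' plots). Empty cells yield empty summaries.
#'
#' @param scores numeric polyp scores.
#' @param labels true labels.
#' @param predictions predicted labels.
#' @return list of per-cell and per-class summaries.
#' @export
score_distribution_summary <- function(scores, labels, predictions) {
  lab <- labels %in% c("yes", TRUE, 1)
  pred <- predictions %in% c("yes", TRUE, 1)
  cell <- ifelse(lab & pred, "TP", ifelse(!lab & !pred, "TN",
                 ifelse(!lab & pred, "FP", "FN")))
  one <- function(v) {
    if (length(v) == 0) {
      return(list(count = 0L, quartiles = c(q1 = NA_real_, median = NA_real_,
                                            q3 = NA_real_), kde = NULL))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    kde <- if (length(unique(v)) >= 2) {
      normalize_and_power(fit_density(v, silverman_bw(v), grid_size = 128), 1)
    } else NULL
    list(count = length(v), quartiles = c(q1 = q[1], median = q[2], q3 = q[3]),
         kde = kde)
  }
  list(
    by_cell = lapply(stats::setNames(nm = c("TP", "TN", "FP", "FN")),
                     function(cl) one(scores[cell == cl])),
    by_class = list(yes = one(scores[lab]), no = one(scores[!lab]))
  )
}
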