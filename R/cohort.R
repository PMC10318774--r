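#' @keywords internal
meta_columns <- function() {
  c("patient_id", "sex", "age", "fit_result", "max_polyp_mm",
    "days_to_colonoscopy", "flags")
}

known_flags <- function() {
  c("repeat_colonoscopy", "prior_colorectal_surgery", "ibd", "fap_or_lynch")
}

#' Read a cohort CSV
#'
#' One row per patient checkup + colonoscopy outcome. The fixed metadata
#' columns are `patient_id`, `sex` (`male`/`female`), `age` (years),
#' `fit_result` (`positive`/`negative`/`missing`), `max_polyp_mm` (largest
#' polyp diameter in mm, 0 = none; recorded polyps start at 1 mm),
#' `days_to_colonoscopy`, and `flags` (semicolon-joined exclusion flags);
#' every schema feature must have its own column. Unparseable numeric cells
#' become `NA`; row order is preserved.
#'
#' @param path CSV path (comma-separated, UTF-8, header row mandatory).
#' @param schema a [feature_schema()]; defaults to [default_schema()].
#' @return A `data.frame` of patient records with class `cohort`.
#' @export
read_cohort_csv <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (file.size(path) == 0) stop("cohort file is empty: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  need <- c(meta_columns(), schema$name)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(
    patient_id = df$patient_id,
    sex = df$sex,
    age = as.integer(num(df$age)),
    fit_result = ifelse(df$fit_result %in% c("positive", "negative"),
                        df$fit_result, "missing"),
    max_polyp_mm = as.integer(num(df$max_polyp_mm)),
    days_to_colonoscopy = as.integer(num(df$days_to_colonoscopy)),
    flags = df$flags,
    stringsAsFactors = FALSE
  )
  for (f in schema$name) out[[f]] <- num(df[[f]])
  class(out) <- c("cohort", "data.frame")
  out
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort_csv()]; uses the same column dialect.
#'
#' @param records a cohort `data.frame`.
#' @param path output path.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

has_flag <- function(records, flag) {
  vapply(strsplit(ifelse(is.na(records$flags), "", records$flags), ";",
                  fixed = TRUE),
         function(fl) flag %in% fl, logical(1))
}

#' Eligibility filtering with a cohort-flow tally
#'
#' Removes ineligible records in a fixed stage order: repeat colonoscopy,
#' prior colorectal surgery, inflammatory bowel disease, FAP/Lynch syndrome,
#' age at or below 20, and colonoscopy more than 365 days after the checkup.
#' A record with several flags is counted only at its first matching stage,
#' so the stage counts are disjoint and sum with the eligible count to the
#' input size.
#'
#' @param records a cohort `data.frame`.
#' @return A list with `eligible` (the surviving records) and `flow`, a
#'   named list of stage counts (class `cohort_flow`).
#' @export
apply_eligibility <- function(records) {
  n0 <- nrow(records)
  stage <- rep("eligible", n0)
  if (n0 > 0) {
    stage[records$days_to_colonoscopy > 365] <- "window_excluded"
    stage[is.na(records$age) | records$age <= 20] <- "age_excluded"
    stage[has_flag(records, "fap_or_lynch")] <- "fap_excluded"
    stage[has_flag(records, "ibd")] <- "ibd_excluded"
    stage[has_flag(records, "prior_colorectal_surgery")] <- "surgery_excluded"
    stage[has_flag(records, "repeat_colonoscopy")] <- "repeat_excluded"
  }
  eligible <- records[stage == "eligible", , drop = FALSE]
  ctx <- attr(records, "screening_context")
  flow <- list(
    screened = if (is.null(ctx)) NA_integer_ else ctx$screened,
    fit_positive_screened = if (is.null(ctx)) NA_integer_ else
      ctx$fit_positive_screened,
    colonoscopy_within_365d = n0 - sum(stage == "window_excluded"),
    repeat_excluded = sum(stage == "repeat_excluded"),
    surgery_excluded = sum(stage == "surgery_excluded"),
    ibd_excluded = sum(stage == "ibd_excluded"),
    fap_excluded = sum(stage == "fap_excluded"),
    age_excluded = sum(stage == "age_excluded"),
    window_excluded = sum(stage == "window_excluded"),
    eligible = nrow(eligible),
    eligible_male = sum(eligible$sex == "male"),
    eligible_female = sum(eligible$sex == "female"),
    fit_positive_eligible = sum(eligible$fit_result == "positive")
  )
  class(flow) <- "cohort_flow"
  list(eligible = eligible, flow = flow)
}

#' Polyp-size tally at nested thresholds
#'
#' @param records a cohort `data.frame`.
#' @param thresholds millimetre cutoffs.
#' @return Named integer vector of counts with `max_polyp_mm >= t`.
#' @export
polyp_size_counts <- function(records, thresholds = c(1, 6, 8, 10)) {
  vapply(thresholds, function(t) sum(records$max_polyp_mm >= t), integer(1)) |>
    stats::setNames(paste0("ge_", thresholds, "mm"))
}

#' Discard records with implausible feature values
#'
#' Any record with a feature value strictly above that feature's
#' `discard_upper_limit` is removed. Removal counts per feature are attached
#' as attribute `"discarded"`.
#'
#' @param records a cohort `data.frame`.
#' @param schema a `feature_schema` whose limits to apply.
#' @return The surviving records.
#' @export
apply_discard_limits <- function(records, schema = default_schema()) {
  keep <- rep(TRUE, nrow(records))
  discarded <- integer(0)
  for (i in seq_len(nrow(schema))) {
    lim <- schema$discard_upper_limit[i]
    if (is.na(lim)) next
    f <- schema$name[i]
    over <- !is.na(records[[f]]) & records[[f]] > lim
    discarded[f] <- sum(over & keep)
    keep <- keep & !over
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "discarded") <- discarded
  out
}

#' Label a cohort at a polyp-size threshold
#'
#' A patient is labelled `"yes"` when the maximum recorded polyp diameter is
#' at or above the threshold; patients with only sub-threshold polyps are
#' grouped with polyp-free patients as `"no"`. Threshold 0 means any
#' recorded polyp (sizes start at 1 mm).
#'
#' @param records a cohort `data.frame`.
#' @param threshold_mm one of 0, 6, 8, 10.
#' @param schema a `feature_schema`; its features become the design matrix.
#' @return A list of class `labeled_dataset` with `x` (feature data.frame),
#'   `y` (factor `no`/`yes`), `sex`, `threshold_mm`, `fit_result` and
#'   `patient_id`.
#' @export
make_labels <- function(records, threshold_mm, schema = default_schema()) {
  if (!threshold_mm %in% c(0, 6, 8, 10)) {
    stop("unsupported polyp size threshold: ", threshold_mm,
         " (supported: 0, 6, 8, 10)")
  }
  cut <- max(threshold_mm, 1)
  y <- factor(ifelse(records$max_polyp_mm >= cut, "yes", "no"),
              levels = c("no", "yes"))
  ds <- list(
    x = as.data.frame(records)[, schema$name, drop = FALSE],
    y = y,
    sex = records$sex,
    threshold_mm = threshold_mm,
    fit_result = records$fit_result,
    patient_id = records$patient_id,
    note = sprintf("labels: max_polyp_mm >= %d mm", cut)
  )
  class(ds) <- "labeled_dataset"
  ds
}

subset_dataset <- function(ds, idx) {
  out <- ds
  out$x <- ds$x[idx, , drop = FALSE]
  out$y <- ds$y[idx]
  out$sex <- ds$sex[idx]
  out$fit_result <- ds$fit_result[idx]
  out$patient_id <- ds$patient_id[idx]
  out
}

#' Stratified train/test split
#'
#' @param dataset a `labeled_dataset`.
#' @param test_fraction in (0, 1).
#' @param seed integer RNG seed; the split is reproducible.
#' @return List with `train` and `test` datasets and the `test_idx`.
#' @export
split_train_test <- function(dataset, test_fraction = 0.25, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  tab <- table(dataset$y)
  if (any(tab < 2)) {
    stop("stratified split needs at least 2 members per class; got ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  test_idx <- withr::with_seed(seed, {
    unlist(lapply(levels(dataset$y), function(cl) {
      idx <- which(dataset$y == cl)
      sample(idx, round(length(idx) * test_fraction))
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  list(train = subset_dataset(dataset, -test_idx),
       test = subset_dataset(dataset, test_idx),
       test_idx = test_idx)
}

#' Median imputation learned on training data
#'
#' Computes per-feature medians on the training design matrix (optionally
#' per sex) and fills missing values in any dataset with those training
#' medians, so no information flows from test to train.
#'
#' @param train_x training design data.frame.
#' @return A named numeric vector of medians.
#' @export
impute_medians <- function(train_x) {
  vapply(train_x, function(v) {
    m <- stats::median(v, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }, numeric(1))
}

#' @rdname impute_medians
#' @param x design data.frame to fill.
#' @param medians vector from `impute_medians`.
#' @export
apply_imputation <- function(x, medians) {
  for (f in names(medians)) {
    miss <- is.na(x[[f]])
    if (any(miss)) x[[f]][miss] <- medians[[f]]
  }
  x
}
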