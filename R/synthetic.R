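base_feature_params <- function() {
  # location/scale of the polyp-free class; lognormal rows interpret
  # location on the natural scale (meanlog = log(location)) and scale as
  # sdlog. Values mirror typical Japanese adult checkup panels.
  p <- rbind(
    data.frame(name = "age",               family = "normal",    location = 60,   scale = 9),
    data.frame(name = "height",            family = "normal",    location = 163,  scale = 9),
    data.frame(name = "weight",            family = "normal",    location = 62,   scale = 12),
    data.frame(name = "bmi",               family = "normal",    location = 23,   scale = 3.5),
    data.frame(name = "waist_cm",          family = "normal",    location = 83,   scale = 9),
    data.frame(name = "systolic_bp",       family = "normal",    location = 125,  scale = 16),
    data.frame(name = "diastolic_bp",      family = "normal",    location = 77,   scale = 11),
    data.frame(name = "hdl",               family = "normal",    location = 60,   scale = 15),
    data.frame(name = "ldl",               family = "normal",    location = 120,  scale = 30),
    data.frame(name = "triglycerides",     family = "lognormal", location = 110,  scale = 0.5),
    data.frame(name = "total_cholesterol", family = "normal",    location = 205,  scale = 33),
    data.frame(name = "fasting_glucose",   family = "lognormal", location = 98,   scale = 0.15),
    data.frame(name = "hba1c",             family = "normal",    location = 5.7,  scale = 0.5),
    data.frame(name = "ast",               family = "lognormal", location = 22,   scale = 0.35),
    data.frame(name = "alt",               family = "lognormal", location = 22,   scale = 0.5),
    data.frame(name = "ggt",               family = "lognormal", location = 35,   scale = 0.7),
    data.frame(name = "uric_acid",         family = "normal",    location = 5.4,  scale = 1.3),
    data.frame(name = "creatinine",        family = "normal",    location = 0.8,  scale = 0.18),
    data.frame(name = "egfr",              family = "normal",    location = 75,   scale = 14),
    data.frame(name = "hemoglobin",        family = "normal",    location = 14.2, scale = 1.4),
    data.frame(name = "hematocrit",        family = "normal",    location = 42.5, scale = 4),
    data.frame(name = "rbc",               family = "normal",    location = 455,  scale = 40),
    data.frame(name = "wbc",               family = "normal",    location = 5.8,  scale = 1.5),
    data.frame(name = "platelets",         family = "normal",    location = 24,   scale = 5),
    data.frame(name = "mcv",               family = "normal",    location = 92,   scale = 4.5),
    data.frame(name = "mch",               family = "normal",    location = 30.5, scale = 1.8),
    data.frame(name = "total_protein",     family = "normal",    location = 7.2,  scale = 0.4),
    data.frame(name = "albumin",           family = "normal",    location = 4.4,  scale = 0.25),
    data.frame(name = "crp",               family = "lognormal", location = 0.07, scale = 0.9),
    data.frame(name = "total_bilirubin",   family = "lognormal", location = 0.8,  scale = 0.35),
    data.frame(name = "amylase",           family = "lognormal", location = 75,   scale = 0.35),
    data.frame(name = "lymphocyte_pct",    family = "normal",    location = 33,   scale = 7),
    data.frame(name = "neutrophil_pct",    family = "normal",    location = 57,   scale = 8)
  )
  p
}

base_ordinal_probs <- function() {
  list(
    drinking_freq   = c(0.45, 0.30, 0.25),
    drinking_amount = c(0.50, 0.30, 0.20),
    smoking_status  = c(0.55, 0.25, 0.20),
    exercise_habit  = c(0.65, 0.35),
    sleep_adequacy  = c(0.40, 0.60),
    eating_speed    = c(0.25, 0.50, 0.25)
  )
}

#' Generative description of a synthetic checkup cohort
#'
#' The generator emulates a sex-stratified screening cohort whose
#' class-conditional feature distributions overlap heavily: each feature is
#' drawn from its class-conditional law given the record's simulated polyp
#' status, with a class shift `delta` expressed in pooled-standard-deviation
#' units (log-scale for lognormal features, a log-odds tilt per level for
#' ordinal codes). Defaults plant six informative features — age, BMI,
#' waist, HDL (protective, negative shift), gamma-GT and drinking frequency,
#' the obesity/alcohol axis the screening literature implicates — at
#' |delta| = 0.5 against 33 noise features. Polyp prevalence defaults to
#' 0.30 for men and 0.20 for women; polyp sizes follow a categorical law
#' over the 1-5 / 6-7 / 8-9 / >=10 mm bands (uniform integer within band)
#' matching the nested counts of the reference cohort flow; the FIT is drawn
#' with sensitivity 0.30 and specificity 0.90 given polyp status.
#'
#' @param n_male,n_female cohort sizes per sex.
#' @param prevalence_male,prevalence_female fraction with `max_polyp_mm >= 1`.
#' @param delta class-shift magnitude for the informative features, in
#'   pooled-SD units; 0 yields a pure-noise cohort.
#' @param informative names of informative features (HDL, if present, takes
#'   shift `-delta`).
#' @param band_probs probabilities of the four size bands, summing to 1.
#' @param fit_sensitivity,fit_specificity FIT error model given polyp status.
#' @param seed integer seed; the cohort is a pure function of the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_male = 1000, n_female = 1000,
                           prevalence_male = 0.30, prevalence_female = 0.20,
                           delta = 0.5,
                           informative = c("age", "bmi", "waist_cm", "hdl",
                                           "ggt", "drinking_freq"),
                           band_probs = c(337, 97, 20, 93) / 547,
                           fit_sensitivity = 0.30, fit_specificity = 0.90,
                           seed = 1) {
  stopifnot(n_male >= 0, n_female >= 0)
  for (nm in c("prevalence_male", "prevalence_female",
               "fit_sensitivity", "fit_specificity")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("invalid synthetic spec field: ", nm, " must be in [0, 1]")
    }
  }
  if (abs(sum(band_probs) - 1) > 1e-8 || any(band_probs < 0)) {
    stop("invalid synthetic spec field: band_probs must be a probability vector")
  }
  params <- base_feature_params()
  if (any(params$scale <= 0)) stop("invalid synthetic spec field: scale")
  unknown <- setdiff(informative, c(params$name, names(base_ordinal_probs())))
  if (length(unknown) > 0) {
    stop("invalid synthetic spec field: informative names unknown: ",
         paste(unknown, collapse = ", "))
  }
  spec <- list(
    n = c(male = n_male, female = n_female),
    prevalence = c(male = prevalence_male, female = prevalence_female),
    delta = delta,
    informative = informative,
    band_probs = band_probs,
    fit_sensitivity = fit_sensitivity,
    fit_specificity = fit_specificity,
    feature_params = params,
    ordinal_probs = base_ordinal_probs(),
    seed = seed
  )
  class(spec) <- "synthetic_spec"
  spec
}

size_bands <- function() list(`1` = 1:5, `2` = 6:7, `3` = 8:9, `4` = 10:20)

draw_polyp_sizes <- function(status, band_probs) {
  sizes <- integer(length(status))
  n_yes <- sum(status)
  if (n_yes > 0) {
    bands <- size_bands()
    band <- sample.int(4, n_yes, replace = TRUE, prob = band_probs)
    sizes[status] <- vapply(band, function(b) {
      rng <- bands[[b]]
      rng[sample.int(length(rng), 1)]
    }, integer(1))
  }
  sizes
}

draw_features <- function(n, status, spec, sex) {
  out <- list()
  delta_of <- function(nm) {
    if (!nm %in% spec$informative) return(0)
    if (nm == "hdl") -spec$delta else spec$delta
  }
  fp <- spec$feature_params
  for (i in seq_len(nrow(fp))) {
    nm <- fp$name[i]; d <- delta_of(nm)
    # the class effect has a location component (shift of d pooled SDs) and
    # a concentration component: the polyp class clusters in a narrower
    # band (scale / (1 + |d|)), emulating the density-shape differences of
    # real checkup features; both vanish at d = 0
    s_yes <- fp$scale[i] / (1 + abs(d))
    sc <- ifelse(status, s_yes, fp$scale[i])
    if (fp$family[i] == "normal") {
      v <- stats::rnorm(n, fp$location[i] + d * fp$scale[i] * status, sc)
    } else {
      v <- exp(stats::rnorm(n, log(fp$location[i]) + d * fp$scale[i] * status,
                            sc))
    }
    if (nm == "age") v <- pmin(pmax(round(v), 40), 80)
    out[[nm]] <- v
  }
  for (nm in names(spec$ordinal_probs)) {
    p0 <- spec$ordinal_probs[[nm]]
    lv <- seq_along(p0) - 1
    d <- delta_of(nm)
    p1 <- p0 * exp(d * lv); p1 <- p1 / sum(p1)
    v <- integer(n)
    v[!status] <- sample(lv, sum(!status), replace = TRUE, prob = p0)
    v[status] <- sample(lv, sum(status), replace = TRUE, prob = p1)
    out[[nm]] <- v
  }
  as.data.frame(out)
}

#' Generate a synthetic checkup cohort
#'
#' Draws a cohort under a [synthetic_spec()]: polyp status per sex-specific
#' prevalence, polyp size from the banded size law, features from the
#' class-conditional distributions, and a FIT result with the specified
#' sensitivity/specificity. All records are unflagged, aged 40-80, with a
#' colonoscopy within 365 days, so the whole cohort is eligible.
#'
#' @param spec a `synthetic_spec`.
#' @return A `cohort` data.frame, reproducible for a fixed spec.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    parts <- lapply(c("male", "female"), function(sx) {
      n <- spec$n[[sx]]
      if (n == 0) return(NULL)
      status <- stats::runif(n) < spec$prevalence[[sx]]
      sizes <- draw_polyp_sizes(status, spec$band_probs)
      feats <- draw_features(n, status, spec, sx)
      p_pos <- ifelse(status, spec$fit_sensitivity, 1 - spec$fit_specificity)
      fit <- ifelse(stats::runif(n) < p_pos, "positive", "negative")
      cbind(
        data.frame(
          patient_id = sprintf("%s%04d", toupper(substr(sx, 1, 1)), seq_len(n)),
          sex = sx,
          age = as.integer(feats$age),
          fit_result = fit,
          max_polyp_mm = sizes,
          days_to_colonoscopy = sample.int(365, n, replace = TRUE),
          flags = "",
          stringsAsFactors = FALSE
        ),
        # age is both a metadata column and a schema feature; keep one copy
        feats[, setdiff(names(feats), "age"), drop = FALSE]
      )
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    class(out) <- c("cohort", "data.frame")
    out
  })
}

#' Deterministic roster reproducing the reference screening cohort flow
#'
#' A fixed roster of 1290 colonoscopy records encoding the cohort flow of
#' the hospital screening series the pipeline was designed around: 274
#' repeat-colonoscopy, 8 prior-surgery and 5 IBD exclusions leave 1003
#' eligible patients (611 men, 392 women); polyp-size categories nest as
#' 547 (>= 1 mm), 210 (>= 6), 113 (>= 8) and 93 (>= 10); 704 of the
#' eligible are FIT-positive. The screening context (21447 people screened,
#' 1133 FIT-positive) is attached as attribute `"screening_context"`.
#' Feature values are synthetic draws conditional on polyp status; only the
#' tallies above are faithful to the reference series.
#'
#' @return A `cohort` data.frame of 1290 records.
#' @export
fixture_roster <- function() {
  withr::with_seed(20150101, {
    n_eli <- 1003
    sex <- sample(rep(c("male", "female"), c(611, 392)))
    # nested size pool: 456 none, 337 in 1-5, 97 in 6-7, 20 in 8-9, 93 >= 10
    pool <- c(rep(0L, 456),
              rep_len(1:5, 337), rep_len(6:7, 97), rep_len(8:9, 20),
              rep_len(10:20, 93))
    sizes <- sample(pool)
    status <- sizes >= 1
    spec <- synthetic_spec(seed = 0)
    feats <- draw_features(n_eli, status, spec, sex)
    fit <- rep("negative", n_eli)
    # 704 FIT-positives = round(0.702 * 1003), weighted toward polyp carriers
    w <- ifelse(status, 2, 1)
    fit[sample.int(n_eli, 704, prob = w)] <- "positive"
    eligible <- cbind(
      data.frame(
        patient_id = sprintf("E%04d", seq_len(n_eli)),
        sex = sex,
        age = as.integer(feats$age),
        fit_result = fit,
        max_polyp_mm = sizes,
        days_to_colonoscopy = sample.int(365, n_eli, replace = TRUE),
        flags = "",
        stringsAsFactors = FALSE
      ),
      feats[, setdiff(names(feats), "age"), drop = FALSE]
    )
    n_exc <- 287
    exc_status <- stats::runif(n_exc) < 0.4
    exc_feats <- draw_features(n_exc, exc_status, spec,
                               sample(c("male", "female"), n_exc, TRUE))
    excluded <- cbind(
      data.frame(
        patient_id = sprintf("X%04d", seq_len(n_exc)),
        sex = sample(c("male", "female"), n_exc, TRUE),
        age = as.integer(exc_feats$age),
        fit_result = sample(c("positive", "negative"), n_exc, TRUE),
        max_polyp_mm = ifelse(exc_status, 3L, 0L),
        days_to_colonoscopy = sample.int(365, n_exc, replace = TRUE),
        flags = rep(c("repeat_colonoscopy", "prior_colorectal_surgery", "ibd"),
                    c(274, 8, 5)),
        stringsAsFactors = FALSE
      ),
      exc_feats[, setdiff(names(exc_feats), "age"), drop = FALSE]
    )
    roster <- rbind(eligible, excluded)
    roster <- roster[sample.int(nrow(roster)), , drop = FALSE]
    rownames(roster) <- NULL
    attr(roster, "screening_context") <-
      list(screened = 21447L, fit_positive_screened = 1133L)
    class(roster) <- c("cohort", "data.frame")
    roster
  })
}
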