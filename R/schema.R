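#' Feature schema for health-checkup cohorts
#'
#' A schema describes the measurement columns of a cohort: name, kind
#' (continuous lab value or small-integer ordinal lifestyle code), units,
#' an optional upper limit above which a record is discarded as implausible,
#' and the direction in which the polyp-positive KDE saturates for the
#' sigmoid-like transform (`"lower"`, `"higher"`, or `"auto"` to infer from
#' class medians on training data).
#'
#' @param name character vector of unique feature names.
#' @param kind `"continuous"` or `"ordinal"` per feature.
#' @param units free-text units per feature.
#' @param discard_upper_limit numeric per feature; `NA` for no limit.
#' @param kde_direction `"lower"`, `"higher"` or `"auto"` per feature.
#' @return A `data.frame` with class `feature_schema`, one row per feature.
#' @export
feature_schema <- function(name, kind = "continuous", units = "",
                           discard_upper_limit = NA_real_,
                           kde_direction = "auto") {
  if (anyDuplicated(name)) stop("feature names must be unique")
  sc <- data.frame(
    name = as.character(name),
    kind = rep_len(kind, length(name)),
    units = rep_len(units, length(name)),
    discard_upper_limit = rep_len(as.numeric(discard_upper_limit), length(name)),
    kde_direction = rep_len(kde_direction, length(name)),
    stringsAsFactors = FALSE
  )
  stopifnot(all(sc$kind %in% c("continuous", "ordinal")),
            all(sc$kde_direction %in% c("lower", "higher", "auto")))
  class(sc) <- c("feature_schema", "data.frame")
  sc
}

#' Default 39-feature checkup schema
#'
#' The default roster of measurements a colorectal-screening checkup panel
#' records: anthropometry, blood pressure, lipid profile, glycaemia, liver
#' and kidney panels, blood counts, inflammation markers, and ordinal
#' lifestyle codes (drinking, smoking, exercise, sleep, eating habits).
#' Discard limits mark values above physiological plausibility for a
#' routine asymptomatic checkup; features without a limit carry `NA`.
#'
#' @return A `feature_schema` with 39 rows.
#' @export
default_schema <- function() {
  cont <- c(
    age                = "years",
    height             = "cm",
    weight             = "kg",
    bmi                = "kg/m2",
    waist_cm           = "cm",
    systolic_bp        = "mmHg",
    diastolic_bp       = "mmHg",
    hdl                = "mg/dL",
    ldl                = "mg/dL",
    triglycerides      = "mg/dL",
    total_cholesterol  = "mg/dL",
    fasting_glucose    = "mg/dL",
    hba1c              = "%",
    ast                = "U/L",
    alt                = "U/L",
    ggt                = "U/L",
    uric_acid          = "mg/dL",
    creatinine         = "mg/dL",
    egfr               = "mL/min/1.73m2",
    hemoglobin         = "g/dL",
    hematocrit         = "%",
    rbc                = "10^4/uL",
    wbc                = "10^3/uL",
    platelets          = "10^4/uL",
    mcv                = "fL",
    mch                = "pg",
    total_protein      = "g/dL",
    albumin            = "g/dL",
    crp                = "mg/dL",
    total_bilirubin    = "mg/dL",
    amylase            = "U/L",
    lymphocyte_pct     = "%",
    neutrophil_pct     = "%"
  )
  ordn <- c(
    drinking_freq   = "0=none,1=sometimes,2=daily",
    drinking_amount = "0/1/2 increasing",
    smoking_status  = "0=never,1=past,2=current",
    exercise_habit  = "0=no,1=yes",
    sleep_adequacy  = "0=no,1=yes",
    eating_speed    = "0=slow,1=normal,2=fast"
  )
  sc <- feature_schema(
    name  = c(names(cont), names(ordn)),
    kind  = c(rep("continuous", length(cont)), rep("ordinal", length(ordn))),
    units = c(unname(cont), unname(ordn))
  )
  # data-cleaning upper limits for a handful of labs where extreme values
  # indicate acute illness or entry error rather than screening-relevant state
  lim <- c(triglycerides = 1000, fasting_glucose = 400, hba1c = 15,
           ast = 300, alt = 300, ggt = 500, crp = 10, creatinine = 5,
           amylase = 500)
  sc$discard_upper_limit[match(names(lim), sc$name)] <- unname(lim)
  # HDL is protective: polyp-positive density peaks at the low end
  sc$kde_direction[sc$name == "hdl"] <- "lower"
  sc
}

#' Read or write a feature schema as JSON
#'
#' @param path file path.
#' @param schema a `feature_schema`.
#' @return `read_schema_json` returns a `feature_schema`.
#' @export
read_schema_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  feature_schema(df$name, df$kind, df$units,
                 df$discard_upper_limit, df$kde_direction)
}

#' @rdname read_schema_json
#' @export
write_schema_json <- function(schema, path) {
  jsonlite::write_json(as.data.frame(schema), path, na = "null",
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}
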