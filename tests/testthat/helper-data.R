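# Builders for small in-code fixtures shared across test files.

# A minimal labeled dataset with planted informative features: the first
# `p_info` features carry a class shift of `delta` pooled SDs, the rest are
# pure noise. Labels are drawn at the given prevalence.
planted_dataset <- function(n = 200, p_info = 2, p_noise = 3, delta = 1,
                            prevalence = 0.4, seed = 1, threshold_mm = 0) {
  withr::with_seed(seed, {
    y <- factor(ifelse(stats::runif(n) < prevalence, "yes", "no"),
                levels = c("no", "yes"))
    p <- p_info + p_noise
    x <- as.data.frame(matrix(stats::rnorm(n * p), n, p))
    names(x) <- c(sprintf("info%d", seq_len(p_info)),
                  sprintf("noise%d", seq_len(p_noise)))
    for (j in seq_len(p_info)) {
      x[[j]] <- x[[j]] + delta * (y == "yes")
    }
    ds <- list(x = x, y = y, sex = rep("male", n), threshold_mm = threshold_mm,
               fit_result = rep("negative", n),
               patient_id = sprintf("T%04d", seq_len(n)),
               note = "planted test dataset")
    class(ds) <- "labeled_dataset"
    ds
  })
}

# schema matching planted_dataset columns
planted_schema <- function(p_info = 2, p_noise = 3) {
  feature_schema(c(sprintf("info%d", seq_len(p_info)),
                   sprintf("noise%d", seq_len(p_noise))))
}

# A tiny hand-built cohort data.frame over an arbitrary schema
tiny_cohort <- function(sizes, sex = "male", flags = "", days = 30, age = 55,
                        fit = "negative", schema = tiny_schema()) {
  n <- length(sizes)
  df <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    sex = rep_len(sex, n),
    age = rep_len(age, n),
    fit_result = rep_len(fit, n),
    max_polyp_mm = as.integer(sizes),
    days_to_colonoscopy = rep_len(days, n),
    flags = rep_len(flags, n),
    stringsAsFactors = FALSE
  )
  for (f in schema$name) if (f != "age") df[[f]] <- seq_len(n) + 0.5
  class(df) <- c("cohort", "data.frame")
  df
}

tiny_schema <- function() {
  feature_schema(c("age", "triglycerides", "hdl"),
                 units = c("years", "mg/dL", "mg/dL"))
}
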