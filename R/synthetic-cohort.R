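#' Cohort marginal targets
#'
#' Marginal structure of the synthetic patient table, defaulting to the
#' study-cohort profile of a 132-participant cardiology sample: 98 men
#' and 34 women, ages 28-68, mean blood pressure 129.93 mmHg within
#' [94, 200], cholesterol within [126, 341], 43.18% alcohol use, 31.06%
#' diabetes, 55.30% smokers, ECG changes in 37.12%. Rates not reported
#' for the cohort (chest pain; cholesterol mean/spread; blood-pressure
#' spread) use conventional cardiology-clinic values.
#'
#' @param sex_male,chest_pain,alcohol,diabetes,ecg_change,smoking
#'   binary-column rates in \[0, 1\].
#' @param age_range integer age bounds (years).
#' @param bp_mean,bp_sd,bp_range blood-pressure mean, spread and
#'   truncation bounds (mmHg).
#' @param chol_mean,chol_sd,chol_range cholesterol mean, spread and
#'   truncation bounds (mg/dL).
#' @return A list of class `cohort_marginals`.
#' @export
cohort_marginals <- function(sex_male = 98 / 132, chest_pain = 0.55,
                             alcohol = 0.4318, diabetes = 0.3106,
                             smoking = 0.5530, ecg_change = 0.3712,
                             age_range = c(28, 68),
                             bp_mean = 129.93, bp_sd = 15, bp_range = c(94, 200),
                             chol_mean = 233, chol_sd = 40,
                             chol_range = c(126, 341)) {
  for (nm in c("sex_male", "chest_pain", "alcohol", "diabetes", "smoking",
               "ecg_change")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stopf("rate '%s' must lie in [0, 1]", nm)
  }
  for (nm in c("age_range", "bp_range", "chol_range")) {
    v <- get(nm)
    if (length(v) != 2L || v[1] >= v[2]) stopf("'%s' must be a valid range", nm)
  }
  if (bp_sd <= 0 || chol_sd <= 0) stopf("spreads must be positive")
  structure(list(sex_male = sex_male, chest_pain = chest_pain,
                 alcohol = alcohol, diabetes = diabetes, smoking = smoking,
                 ecg_change = ecg_change, age_range = age_range,
                 bp_mean = bp_mean, bp_sd = bp_sd, bp_range = bp_range,
                 chol_mean = chol_mean, chol_sd = chol_sd,
                 chol_range = chol_range),
            class = "cohort_marginals")
}

# truncated normal whose *truncated* mean equals `target`: the latent
# mean is solved with uniroot so asymmetric bounds introduce no bias
rtnorm_mean <- function(n, target, sd, range) {
  tmean <- function(mu) {
    a <- (range[1] - mu) / sd; b <- (range[2] - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  mu <- uniroot(function(m) tmean(m) - target,
                lower = range[1], upper = range[2], tol = 1e-8)$root
  x <- rnorm(n, mu, sd)
  bad <- x < range[1] | x > range[2]
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mu, sd)
    bad <- x < range[1] | x > range[2]
  }
  x
}

# logistic-link coefficients for the synthetic condition outcome;
# continuous features enter standardized (see vignette)
condition_coefs <- function() {
  c(age = 0.8, sex = 0.3, chest_pain = 0.6, blood_pressure = 0.7,
    cholesterol = 0.6, alcohol = 0.3, diabetes = 0.7, ecg_change = 0.8,
    smoking = 0.5)
}

patient_columns <- function()
  c("Age", "Sex", "Chest Pain", "Blood Pressure", "Cholesterol",
    "Alcohol", "Diabetes", "ECG Change", "Smoking", "Condition")

#' Generate a synthetic patient table
#'
#' Draws a patient cohort with the requested marginal structure:
#' binary risk factors as independent Bernoulli draws, ages uniform on
#' the configured range, blood pressure and cholesterol from truncated
#' normals whose truncated means match the configured targets. The
#' binary condition outcome is generated from a documented logistic
#' link on the standardized continuous features plus the binary risk
#' factors (coefficients in `ecgflow:::condition_coefs()`), so
#' classifiers have real signal to find.
#'
#' With `link = "threshold"` the outcome is instead the deterministic
#' sign of the linear score, and rows whose |score| falls below
#' `margin` are redrawn: the result is a linearly separable cohort with
#' a wide margin, useful as a positive control for model comparisons.
#'
#' @param n number of patients, `n >= 1` (default 132).
#' @param marginals a [cohort_marginals()].
#' @param seed integer seed; same seed, same table.
#' @param link `"logistic"` (default) or `"threshold"`.
#' @param margin margin half-width for `link = "threshold"` in score
#'   units (default 2.5, about 1.8 standard deviations of the score on
#'   each side of the boundary -- a wide margin).
#' @return Data frame with exactly the columns Age, Sex, Chest Pain,
#'   Blood Pressure, Cholesterol, Alcohol, Diabetes, ECG Change,
#'   Smoking, Condition.
#' @export
generate_patient_table <- function(n = 132, marginals = cohort_marginals(),
                                   seed = 1L, link = c("logistic", "threshold"),
                                   margin = 2.5) {
  check_number(n, "n", 1)
  if (n != floor(n)) stopf("'n' must be an integer")
  stopifnot(inherits(marginals, "cohort_marginals"))
  link <- match.arg(link)
  m <- marginals
  with_seed(seed, {
    draw <- function(nn) {
      data.frame(
        Age = sample(seq(m$age_range[1], m$age_range[2]), nn, replace = TRUE),
        Sex = rbinom(nn, 1, m$sex_male),
        `Chest Pain` = rbinom(nn, 1, m$chest_pain),
        `Blood Pressure` = round(rtnorm_mean(nn, m$bp_mean, m$bp_sd, m$bp_range)),
        Cholesterol = round(rtnorm_mean(nn, m$chol_mean, m$chol_sd, m$chol_range)),
        Alcohol = rbinom(nn, 1, m$alcohol),
        Diabetes = rbinom(nn, 1, m$diabetes),
        `ECG Change` = rbinom(nn, 1, m$ecg_change),
        Smoking = rbinom(nn, 1, m$smoking),
        check.names = FALSE)
    }
    score <- function(df) {
      b <- condition_coefs()
      zs <- function(x, mean, sd) (x - mean) / sd
      lin <- b[["age"]] * zs(df$Age, mean(m$age_range), diff(m$age_range) / sqrt(12)) +
        b[["blood_pressure"]] * zs(df$`Blood Pressure`, m$bp_mean, m$bp_sd) +
        b[["cholesterol"]] * zs(df$Cholesterol, m$chol_mean, m$chol_sd) +
        b[["sex"]] * df$Sex + b[["chest_pain"]] * df$`Chest Pain` +
        b[["alcohol"]] * df$Alcohol + b[["diabetes"]] * df$Diabetes +
        b[["ecg_change"]] * df$`ECG Change` + b[["smoking"]] * df$Smoking
      # intercept centres the prevalence near one half
      lin - (b[["sex"]] * m$sex_male + b[["chest_pain"]] * m$chest_pain +
             b[["alcohol"]] * m$alcohol + b[["diabetes"]] * m$diabetes +
             b[["ecg_change"]] * m$ecg_change + b[["smoking"]] * m$smoking)
    }
    df <- draw(n)
    z <- score(df)
    if (link == "logistic") {
      df$Condition <- rbinom(n, 1, plogis(z))
    } else {
      # redraw rows inside the margin band until the cohort is separable
      for (it in 1:200) {
        inside <- abs(z) < margin
        if (!any(inside)) break
        repl <- draw(sum(inside))
        df[inside, names(repl)] <- repl
        z[inside] <- score(repl)
      }
      if (any(abs(z) < margin))
        stopf("could not realise a margin of %g; lower 'margin'", margin)
      df$Condition <- as.integer(z > 0)
    }
    df
  })
}
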