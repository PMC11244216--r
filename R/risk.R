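#' Validate a patient table
#'
#' Checks the ten-column patient schema (Age, Sex, Chest Pain, Blood
#' Pressure, Cholesterol, Alcohol, Diabetes, ECG Change, Smoking,
#' Condition): no missing values, binary columns in {0, 1}, positive
#' age, blood pressure and cholesterol.
#'
#' @param table data frame in the patient schema.
#' @return The validated table (invisibly usable downstream).
#' @export
validate_patient_table <- function(table) {
  df <- as.data.frame(table, check.names = FALSE)
  miss <- setdiff(patient_columns(), names(df))
  if (length(miss))
    stopf("patient table is missing column(s): %s", paste(miss, collapse = ", "))
  df <- df[, patient_columns()]
  if (anyNA(df)) stopf("patient table contains missing values")
  for (cn in c("Sex", "Chest Pain", "Alcohol", "Diabetes", "ECG Change",
               "Smoking", "Condition"))
    if (!all(df[[cn]] %in% c(0, 1))) stopf("column '%s' must be binary 0/1", cn)
  for (cn in c("Age", "Blood Pressure", "Cholesterol"))
    if (!all(df[[cn]] > 0)) stopf("column '%s' must be positive", cn)
  df
}

patient_feature_columns <- function() setdiff(patient_columns(), "Condition")

#' Z-score standardization of patient features
#'
#' Scales each of the nine feature columns (the condition outcome is
#' excluded) to sample mean 0 and standard deviation 1. When `params`
#' is supplied (means/sds fitted on a training split) those parameters
#' are applied instead of re-estimating, so held-out folds never leak
#' into the scaler.
#'
#' @param table a patient table.
#' @param params optional list with `mean` and `sd` vectors from a
#'   previous call.
#' @return List with `x` (scaled numeric matrix, columns in schema
#'   order) and `params`.
#' @export
standardize_features <- function(table, params = NULL) {
  df <- validate_patient_table(table)
  x <- as.matrix(df[, patient_feature_columns()])
  storage.mode(x) <- "double"
  if (is.null(params)) {
    mu <- colMeans(x)
    s <- apply(x, 2, sd)
    if (any(s == 0))
      stopf("zero-variance feature column(s): %s",
            paste(colnames(x)[s == 0], collapse = ", "))
    params <- list(mean = mu, sd = s)
  }
  xs <- sweep(sweep(x, 2, params$mean, "-"), 2, params$sd, "/")
  list(x = xs, params = params)
}

#' Pearson correlation matrix of the patient table
#'
#' Full 10 x 10 Pearson correlation matrix including the condition
#' outcome. The matrix is symmetric with unit diagonal; correlations
#' involving a constant column are undefined and reported as `NA`.
#'
#' @param table a patient table with at least 3 rows.
#' @return Symmetric numeric matrix with `diag == 1`.
#' @export
correlation_matrix <- function(table) {
  df <- validate_patient_table(table)
  if (nrow(df) < 3) stopf("need at least 3 rows for a correlation matrix")
  m <- suppressWarnings(cor(as.matrix(df), method = "pearson"))
  diag(m) <- 1
  m
}

#' Grouped five-number summaries with outlier fences
#'
#' Boxplot statistics of every feature split by the condition outcome:
#' minimum, first quartile, median, third quartile, maximum (type-7
#' quantiles) plus the values falling outside the 1.5 IQR fences.
#'
#' @param table a patient table in which both condition groups are
#'   non-empty.
#' @return Data frame with one row per (variable, condition) pair:
#'   `min`, `q1`, `median`, `q3`, `max`, `n_outliers`, and a list
#'   column `outliers` with the flagged values.
#' @export
boxplot_summary <- function(table) {
  df <- validate_patient_table(table)
  groups <- sort(unique(df$Condition))
  if (length(groups) < 2) stopf("both condition groups must be non-empty")
  rows <- list()
  for (v in patient_feature_columns()) {
    for (g in groups) {
      vals <- df[[v]][df$Condition == g]
      q <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      iqr <- q[3] - q[1]
      fence <- c(q[1] - 1.5 * iqr, q[3] + 1.5 * iqr)
      out <- vals[vals < fence[1] | vals > fence[2]]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, condition = g, min = min(vals), q1 = q[1],
        median = q[2], q3 = q[3], max = max(vals),
        n_outliers = length(out), outliers = I(list(out)))
    }
  }
  do.call(rbind, rows)
}

risk_model_names <- function()
  c("logistic", "decision_tree", "random_forest", "svm", "xgboost", "cnn")

fit_risk_model <- function(model, x, y, seed) {
  dtrain <- data.frame(x, check.names = TRUE)
  dtrain$.y <- factor(y, levels = c(0, 1))
  switch(model,
    logistic = suppressWarnings(
      glm(.y ~ ., data = dtrain, family = binomial())),
    decision_tree = with_seed(seed,
      rpart::rpart(.y ~ ., data = dtrain, method = "class")),
    random_forest = with_seed(seed,
      randomForest::randomForest(x, factor(y, levels = c(0, 1)), ntree = 200)),
    svm = with_seed(seed,
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                 scale = FALSE)),
    xgboost = with_seed(seed,
      xgboost::xgboost(x, factor(y, levels = c(0, 1)), nrounds = 60,
                       verbosity = 0, nthread = 1, max_depth = 3,
                       learning_rate = 0.3)),
    cnn = cnn_fit(x, y, seed = seed),
    stopf("unknown model '%s'", model))
}

predict_risk_model <- function(model, fit, x) {
  dtest <- data.frame(x, check.names = TRUE)
  switch(model,
    logistic = as.integer(predict(fit, newdata = dtest, type = "response") > 0.5),
    decision_tree = as.integer(as.character(
      predict(fit, newdata = dtest, type = "class"))),
    random_forest = as.integer(as.character(predict(fit, newdata = x))),
    svm = as.integer(as.character(predict(fit, newdata = x))),
    xgboost = as.integer(predict(fit, newdata = x) > 0.5),
    cnn = predict(fit, x, type = "class"))
}

binary_f1 <- function(truth, pred) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  if (2 * tp + fp + fn == 0) {
    warning("F1 undefined (no positives present or predicted); reported as 0")
    return(0)
  }
  2 * tp / (2 * tp + fp + fn)
}

# stratified train/test split; resamples (with a warning) if the test
# fold ends up single-class
stratified_split <- function(y, test_fraction) {
  for (attempt in 1:100) {
    test <- unlist(lapply(split(seq_along(y), y), function(idx) {
      k <- max(1L, round(length(idx) * test_fraction))
      sample(idx, k)
    }), use.names = FALSE)
    if (length(unique(y[test])) > 1 && length(unique(y[-test])) > 1)
      return(sort(test))
    warning("single-class split resampled")
  }
  stopf("could not produce a two-class split")
}

#' Compare classifier families on a patient table
#'
#' Repeated stratified random splits: on each repeat the table is
#' split into training and test subsets, features are z-scored with
#' parameters fitted on the training split only, each requested model
#' is fitted on the training data, and accuracy and F1 (positive class
#' = condition 1) are measured on the test split. The default model
#' set covers the six families of the study design: logistic
#' regression, decision tree, random forest, SVM (RBF), gradient
#' boosted trees and a small 1-D CNN.
#'
#' @param table a patient table.
#' @param models subset of
#'   `c("logistic","decision_tree","random_forest","svm","xgboost","cnn")`.
#' @param repeats number of random splits (default 50).
#' @param test_fraction held-out fraction per split (default 0.2).
#' @param seed integer seed; splits and model fits are derived from it.
#' @return An object of class `risk_report`: list with `results` (one
#'   row per model x split), `summary` (per-model mean and sd of
#'   accuracy and F1) and the configuration.
#' @export
evaluate_models <- function(table, models = risk_model_names(), repeats = 50,
                            test_fraction = 0.2, seed = 1L) {
  df <- validate_patient_table(table)
  models <- match.arg(models, risk_model_names(), several.ok = TRUE)
  check_number(repeats, "repeats", 1)
  check_number(test_fraction, "test_fraction")
  if (test_fraction <= 0 || test_fraction >= 1)
    stopf("'test_fraction' must be in (0, 1)")
  y <- df$Condition
  res <- list()
  for (r in seq_len(repeats)) {
    split_seed <- as.integer(seed) + 7919L * r
    test <- with_seed(split_seed, stratified_split(y, test_fraction))
    train_df <- df[-test, , drop = FALSE]
    test_df <- df[test, , drop = FALSE]
    sc <- standardize_features(train_df)
    x_train <- sc$x
    x_test <- standardize_features(test_df, params = sc$params)$x
    for (m in models) {
      mseed <- split_seed + match(m, risk_model_names())
      fit <- fit_risk_model(m, x_train, y[-test], mseed)
      pred <- predict_risk_model(m, fit, x_test)
      res[[length(res) + 1L]] <- data.frame(
        model = m, split = r,
        accuracy = mean(pred == y[test]),
        f1 = binary_f1(y[test], pred))
    }
  }
  results <- do.call(rbind, res)
  summary <- do.call(rbind, lapply(split(results, results$model), function(d)
    data.frame(model = d$model[1], mean_accuracy = mean(d$accuracy),
               sd_accuracy = sd(d$accuracy), mean_f1 = mean(d$f1),
               sd_f1 = sd(d$f1))))
  summary <- summary[match(models, summary$model), ]
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary,
                 config = list(models = models, repeats = repeats,
                               test_fraction = test_fraction, seed = seed)),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("<risk_report> %d models x %d stratified splits (test fraction %g)\n",
              length(x$config$models), x$config$repeats, x$config$test_fraction))
  s <- x$summary
  s[, -1] <- round(s[, -1], 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
plot.risk_report <- function(x, ...) {
  s <- x$summary
  bp <- graphics::barplot(rbind(s$mean_accuracy, s$mean_f1), beside = TRUE,
                          names.arg = s$model, ylim = c(0, 1), las = 2,
                          ylab = "score", ...)
  legend("bottomright", c("accuracy", "F1"), fill = c("gray30", "gray70"))
  invisible(x)
}
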