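#' Anomaly-model configuration
#'
#' Settings for Isolation Forest labelling of fiducial-table rows:
#' 100 trees, automatic contamination (anomaly threshold at the
#' standard score offset of 0.5 rather than a fitted quantile) and a
#' fixed random state of 42 for reproducible subsampling and splits.
#'
#' Two feature modes are available. `"raw"` feeds the five fiducial
#' index columns as-is, matching the tabulated per-beat schema.
#' Because raw indices grow with recording time, the module also
#' offers `"intervals"`, which derives per-beat durations (PQ, QR, RS,
#' ST in samples, plus the RR interval to the previous beat) that are
#' position-free.
#'
#' @param n_estimators number of trees (default 100).
#' @param contamination only `"auto"` is supported: anomalous when the
#'   isolation score exceeds 0.5.
#' @param random_state integer seed (default 42).
#' @param sample_size per-tree subsample cap (default 256).
#' @param features `"raw"` or `"intervals"`.
#' @return An object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(n_estimators = 100, contamination = "auto",
                         random_state = 42, sample_size = 256,
                         features = c("raw", "intervals")) {
  check_number(n_estimators, "n_estimators")
  if (n_estimators < 1) stopf("'n_estimators' must be >= 1")
  if (!identical(contamination, "auto"))
    stopf("only contamination = \"auto\" is supported")
  features <- match.arg(features)
  structure(list(n_estimators = as.integer(n_estimators),
                 contamination = contamination,
                 random_state = as.integer(random_state),
                 sample_size = sample_size, features = features),
            class = "anomaly_spec")
}

# feature matrix for anomaly scoring; intervals are in samples
fiducial_features <- function(table, mode = "raw") {
  m <- as.matrix(as.data.frame(table)[, fiducial_columns()])
  if (identical(mode, "raw")) return(m)
  rr <- diff(m[, "R_Peaks"])
  rr <- c(if (length(rr)) median(rr) else 0, rr)
  cbind(PQ = m[, "Q_Points"] - m[, "P_Points"],
        QR = m[, "R_Peaks"] - m[, "Q_Points"],
        RS = m[, "S_Points"] - m[, "R_Peaks"],
        ST = m[, "T_Points"] - m[, "S_Points"],
        RR = rr)
}

#' Label anomalous beats in a fiducial table
#'
#' Fits an Isolation Forest to the rows of a fiducial table and
#' appends an `Anomaly` column: +1 for normal rows, -1 for anomalous
#' ones. All input columns and rows are preserved verbatim; repeated
#' calls with the same table and spec give identical labels.
#'
#' @param table a [fiducial_table()] (or data frame with the five
#'   fiducial columns), at least 2 rows, no missing values.
#' @param spec an [anomaly_spec()].
#' @return The input table with an added `Anomaly` column and class
#'   `ecg_anomaly`; isolation scores are kept in the `scores`
#'   attribute.
#' @export
fit_predict_anomalies <- function(table, spec = anomaly_spec()) {
  stopifnot(inherits(spec, "anomaly_spec"))
  df <- as.data.frame(table)
  if (nrow(df) == 0L) stopf("empty fiducial table")
  if (nrow(df) < 2L) stopf("need at least 2 rows to score anomalies")
  feats <- fiducial_features(df, spec$features)
  if (anyNA(feats)) stopf("fiducial table contains missing values")
  fit <- iso_forest(feats, n_trees = spec$n_estimators,
                    sample_size = spec$sample_size, seed = spec$random_state)
  scores <- predict(fit, feats)
  out <- df
  out$Anomaly <- ifelse(scores > 0.5, -1L, 1L)
  attr(out, "scores") <- scores
  attr(out, "spec") <- spec
  class(out) <- unique(c("ecg_anomaly", class(out)))
  out
}

#' Per-label column means
#'
#' Arithmetic mean of each fiducial column within the anomalous
#' (`Anomaly == -1`) and normal (`Anomaly == +1`) groups; a group with
#' no rows is reported as `NA` (undefined), never as zero.
#'
#' @param labeled a table with the five fiducial columns and an
#'   `Anomaly` column, e.g. from [fit_predict_anomalies()].
#' @return Data frame with columns `variable`, `anomalous_mean`,
#'   `normal_mean`; the final row reports the label value itself.
#' @export
summarize_by_label <- function(labeled) {
  df <- as.data.frame(labeled)
  if (nrow(df) == 0L) stopf("empty table")
  if (is.null(df$Anomaly)) stopf("table has no 'Anomaly' column")
  if (!all(df$Anomaly %in% c(-1, 1))) stopf("Anomaly labels must be -1 or +1")
  group_mean <- function(col, lab) {
    v <- df[[col]][df$Anomaly == lab]
    if (length(v)) mean(v) else NA_real_
  }
  vars <- c(fiducial_columns(), "Anomaly")
  data.frame(
    variable = vars,
    anomalous_mean = vapply(vars, group_mean, numeric(1), lab = -1),
    normal_mean = vapply(vars, group_mean, numeric(1), lab = 1),
    row.names = NULL)
}

#' Score anomaly labels against known truth
#'
#' Confusion-matrix metrics with the anomalous label (-1) as the
#' positive class: accuracy, true positive rate (recall on true
#' outliers) and false positive rate.
#'
#' @param labeled output of [fit_predict_anomalies()].
#' @param truth integer vector of true-outlier row numbers (1-based
#'   rows of the table).
#' @return List with `accuracy`, `tpr`, `fpr` and the confusion counts.
#' @export
evaluate_against_truth <- function(labeled, truth) {
  df <- as.data.frame(labeled)
  n <- nrow(df)
  if (length(truth) && (any(truth < 1) || any(truth > n)))
    stopf("truth indices outside the table")
  is_pos <- seq_len(n) %in% truth
  pred_pos <- df$Anomaly == -1
  tp <- sum(pred_pos & is_pos); fp <- sum(pred_pos & !is_pos)
  fn <- sum(!pred_pos & is_pos); tn <- sum(!pred_pos & !is_pos)
  list(accuracy = (tp + tn) / n,
       tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Inject known outliers into a fiducial table
#'
#' Shifts `k` randomly chosen rows of a fiducial table by a fixed
#' offset (all five columns moved together, so within-beat ordering is
#' preserved), creating rows whose position breaks the beat-to-beat
#' rhythm -- a ground-truth outlier set for validating the anomaly
#' detector. The shift direction is drawn per row; a negative shift
#' that would produce negative indices falls back to positive.
#' Unperturbed rows are returned bit-identical.
#'
#' @param table a [fiducial_table()].
#' @param k number of rows to perturb, `0 <= k <= nrow(table)`.
#' @param magnitude offset in samples, > 0.
#' @param seed integer seed.
#' @return List with `table` (perturbed copy) and `outliers` (sorted
#'   perturbed row numbers, 1-based; empty when `k = 0`).
#' @export
inject_fiducial_outliers <- function(table, k, magnitude, seed = 1L) {
  df <- as.data.frame(table)
  check_number(k, "k", 0)
  if (k != floor(k)) stopf("'k' must be an integer")
  if (k > nrow(df)) stopf("'k' (%d) exceeds the row count (%d)", k, nrow(df))
  check_number(magnitude, "magnitude")
  if (magnitude <= 0) stopf("'magnitude' must be positive")
  if (k == 0) return(list(table = table, outliers = integer(0)))
  mag <- as.integer(round(magnitude))
  with_seed(seed, {
    rows <- sort(sample.int(nrow(df), k))
    signs <- sample(c(-1L, 1L), k, replace = TRUE)
    for (i in seq_along(rows)) {
      r <- rows[i]
      delta <- signs[i] * mag
      if (min(df[r, fiducial_columns()]) + delta < 0) delta <- mag
      df[r, fiducial_columns()] <- df[r, fiducial_columns()] + delta
    }
    out <- df
    class(out) <- class(as.data.frame(table))
    list(table = out, outliers = rows)
  })
}
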