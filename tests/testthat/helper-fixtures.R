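# Shared fixtures and oracles, all built in code.

# path to the worked-example labelled-beat excerpt shipped with the package
table3_path <- function() system.file("extdata", "table3_labels.csv",
                                      package = "ecgflow")

# the 11-row worked-example patient excerpt
table5_df <- function() {
  df <- data.frame(
    Age = c(35, 35, 42, 48, 44, 28, 45, 47, 30, 46, 53),
    Sex = c(1, 1, 1, 1, 1, 1, 0, 1, 0, 1, 1),
    `Chest Pain` = rep(1, 11),
    `Blood Pressure` = c(120, 126, 136, 124, 120, 104, 138, 112, 138, 140, 140),
    Cholesterol = c(198, 282, 315, 274, 169, 208, 236, 204, 243, 311, 203),
    Alcohol = c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0, 1),
    Diabetes = c(0, 1, 0, 1, 1, 0, 0, 0, 0, 0, 1),
    `ECG Change` = c(1, 1, 1, 0, 1, 1, 1, 0, 1, 1, 1),
    Smoking = c(1, 0, 1, 1, 1, 1, 1, 0, 1, 1, 1),
    Condition = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 1, 1),
    check.names = FALSE)
  df
}

# noise-free generator settings
clean_config <- function(...) {
  synth_config(white_sd = 0, wander_amp = 0, mains_amp = 0, impulse_rate = 0,
               ...)
}

# FFT amplitude of frequency f in the steady-state middle of a signal
fft_amplitude <- function(x, fs_hz, f) {
  n <- length(x)
  mid <- x[floor(n / 4):(floor(n / 4) + floor(n / 2) - 1)]
  nn <- length(mid)
  sp <- abs(fft(mid)) / nn * 2
  k <- round(f * nn / fs_hz) + 1
  max(sp[max(1, k - 1):min(nn, k + 1)])
}

# worst per-point recovery error, aligning detected beats to truth by
# the nearest R peak
recovery_error <- function(fid, truth) {
  cols <- c("P_Points", "Q_Points", "R_Peaks", "S_Points", "T_Points")
  max(vapply(seq_len(nrow(truth)), function(i) {
    j <- which.min(abs(fid$R_Peaks - truth$R_Peaks[i]))
    max(abs(unlist(fid[j, cols]) - unlist(truth[i, cols])))
  }, numeric(1)))
}

# brute-force Pearson correlation from the definition
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# injected-outlier detection suite; returns pooled TP and positives
outlier_suite <- function(seeds, ks, magnitude_factor) {
  tp <- 0L; pos <- 0L
  spec <- anomaly_spec(features = "intervals")
  for (i in seq_along(seeds)) {
    g <- generate_ecg(clean_config(duration = 52, seed = seeds[i]))
    tab <- g$truth[1:50, ]
    rr <- diff(tab$R_Peaks)
    spread <- sd(rr)
    inj <- inject_fiducial_outliers(tab, ks[i], magnitude_factor * spread,
                                    seed = seeds[i] + 1000L)
    ev <- evaluate_against_truth(fit_predict_anomalies(inj$table, spec),
                                 inj$outliers)
    tp <- tp + ev$tp; pos <- pos + ev$tp + ev$fn
  }
  c(tp = tp, pos = pos)
}
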