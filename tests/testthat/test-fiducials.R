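test_that("window durations convert to the canonical sample counts", {
  expect_equal(window_samples(0.04, 360), 14.4)
  expect_equal(window_samples(0.08, 360), 28.8)
  expect_equal(window_samples(0.2, 360), 72)
  expect_error(window_samples(-0.1, 360), "positive")
  expect_error(fiducial_windows(p_win_near = 0.3, p_win_far = 0.2), "exceed")
})

test_that("R peaks are recovered on a clean rhythm and absent on silence", {
  g <- generate_ecg(clean_config(duration = 10, heart_rate = 60, seed = 31))
  r <- detect_r_peaks(g$signal)
  expect_true(length(r) %in% c(9, 10))
  expect_true(all(diff(r) >= 0.2 * 360))
  for (tr in g$truth$R_Peaks) expect_lte(min(abs(r - tr)), 2)

  expect_identical(detect_r_peaks(ecg_signal(rep(0, 3600), 360)), integer(0))
  expect_identical(detect_r_peaks(ecg_signal(rnorm(10), 360)), integer(0))
})

test_that("ties between identical adjacent maxima keep the earlier index", {
  x <- c(rep(0, 200), 0.2, 1, 1, 0.2, rep(0, 200))
  r <- detect_r_peaks(ecg_signal(x, 360), threshold_factor = 1.0)
  expect_identical(r, 201L)   # 0-based index of the first plateau sample
})

test_that("fiducials recover ground truth within 3 samples across rates", {
  for (hr in c(40, 100, 180)) {
    g <- generate_ecg(clean_config(duration = 15, heart_rate = hr, seed = hr))
    r <- detect_r_peaks(g$signal)
    fid <- suppressWarnings(detect_fiducials(g$signal, r))
    expect_equal(nrow(fid), nrow(g$truth))
    expect_lte(recovery_error(fid, g$truth), 3)
  }
})

test_that("every emitted row satisfies ordering and window bounds", {
  g <- generate_ecg(synth_config(duration = 20, heart_rate = 75, seed = 44))
  sig <- preprocess_signal(g$signal)
  fid <- suppressWarnings(detect_fiducials(sig, detect_r_peaks(sig)))
  expect_gt(nrow(fid), 5)
  expect_true(all(fid$P_Points < fid$Q_Points & fid$Q_Points < fid$R_Peaks &
                  fid$R_Peaks < fid$S_Points & fid$S_Points < fid$T_Points))
  expect_true(all(fid$R_Peaks - fid$Q_Points <= 14))
  expect_true(all(fid$S_Points - fid$R_Peaks <= 28))
  expect_true(all(fid$T_Points - fid$S_Points <= 72))
  expect_true(all(fid$Q_Points - fid$P_Points >= 43 &
                  fid$Q_Points - fid$P_Points <= 72))
})

test_that("argmin/argmax in each window agree with an exhaustive scan", {
  g <- generate_ecg(synth_config(duration = 10, seed = 9))
  x <- as.numeric(g$signal)
  fid <- suppressWarnings(detect_fiducials(g$signal, detect_r_peaks(g$signal)))
  scan_extreme <- function(lo, hi, f) {
    best <- lo
    for (i in lo:hi) if (f(x[i + 1], x[best + 1])) best <- i
    best
  }
  for (j in seq_len(nrow(fid))) {
    r <- fid$R_Peaks[j]
    expect_equal(fid$Q_Points[j],
                 scan_extreme(r - 14, r - 1, function(a, b) a < b))
    expect_equal(fid$S_Points[j],
                 scan_extreme(r + 1, r + 28, function(a, b) a < b))
    s <- fid$S_Points[j]
    expect_equal(fid$T_Points[j],
                 scan_extreme(s + 1, s + 72, function(a, b) a > b))
    q <- fid$Q_Points[j]
    expect_equal(fid$P_Points[j],
                 scan_extreme(q - 72, q - 43, function(a, b) a > b))
  }
})

test_that("detection is equivariant to positive amplitude scaling", {
  g <- generate_ecg(clean_config(duration = 10, seed = 23))
  f1 <- suppressWarnings(detect_fiducials(g$signal, detect_r_peaks(g$signal)))
  scaled <- ecg_signal(5.5 * as.numeric(g$signal), fs(g$signal))
  f2 <- suppressWarnings(detect_fiducials(scaled, detect_r_peaks(scaled)))
  expect_identical(as.data.frame(f1), as.data.frame(f2))
})

test_that("empty peak lists and edge beats are handled gracefully", {
  g <- generate_ecg(clean_config(duration = 10, seed = 2))
  empty <- detect_fiducials(g$signal, integer(0))
  expect_s3_class(empty, "fiducial_table")
  expect_identical(nrow(empty), 0L)
  # an R peak too close to the start must be dropped, not mis-delineated
  expect_warning(out <- detect_fiducials(g$signal, c(10L, g$truth$R_Peaks)),
                 "dropped")
  expect_equal(nrow(out), nrow(g$truth))
})

test_that("fiducial table invariants are enforced by the constructor", {
  good <- data.frame(Q_Points = 10L, R_Peaks = 20L, S_Points = 30L,
                     T_Points = 40L, P_Points = 1L)
  expect_s3_class(fiducial_table(good), "fiducial_table")
  bad <- good; bad$S_Points <- 15L   # S before R
  expect_error(fiducial_table(bad), "ordering")
  expect_error(fiducial_table(good[, -1]), "missing")
  expect_error(fiducial_table(good, signal_length = 30), "exceed")
})
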