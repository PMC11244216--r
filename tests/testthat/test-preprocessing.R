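test_that("magnitude response halves at the cut-off and is monotone", {
  for (n in 1:6) expect_equal(response_magnitude(50, 50, n), 0.5)
  expect_equal(response_magnitude(0, 40), 1.0)
  expect_equal(response_magnitude(80, 40, 1), 0.2)   # 1 / (1 + 2^2)

  f_grid <- seq(0, 150, by = 2.5)
  for (n in c(1, 2, 4)) {
    g <- response_magnitude(f_grid, fc = 35, n = n)
    expect_true(all(diff(g) < 0 | f_grid[-1] == 0))
    expect_true(all(g > 0 & g <= 1))
  }
  # monotone increasing in fc at fixed f
  gains <- vapply(c(10, 20, 40, 80), function(fc)
    response_magnitude(30, fc, 2), numeric(1))
  expect_true(all(diff(gains) > 0))
  expect_error(response_magnitude(10, -1), "positive")
})

test_that("band-pass preserves the passband and removes drift and DC", {
  fs_hz <- 360
  t <- (0:(20 * fs_hz - 1)) / fs_hz
  in_band <- ecg_signal(sin(2 * pi * 10 * t), fs_hz)
  out10 <- bandpass_filter(in_band)
  expect_length(out10, length(in_band))
  expect_lt(abs(fft_amplitude(as.numeric(out10), fs_hz, 10) - 1), 0.05)

  drift <- ecg_signal(sin(2 * pi * 0.1 * t), fs_hz)
  expect_lt(max(abs(bandpass_filter(drift)[(5 * fs_hz):(15 * fs_hz)])), 0.1)

  # DC is below the low cut: removed once the start-up transient of the
  # 0.5 Hz high-pass edge (time constant ~2 s) has decayed
  const <- ecg_signal(rep(2.5, 30 * fs_hz), fs_hz)
  mid <- bandpass_filter(const)[(10 * fs_hz):(20 * fs_hz)]
  expect_lt(max(abs(mid)), 0.01)

  expect_error(filter_spec(f_hi = 200, fs = 360), "Nyquist")
  expect_error(filter_spec(f_lo = 0), "positive")
})

test_that("median filter removes impulses, keeps monotone runs, identity at 1", {
  s <- ecg_signal(c(0, 0, 5, 0, 0), 360)
  expect_equal(as.numeric(median_filter(s, 3)), rep(0, 5))

  mono <- ecg_signal(cumsum(runif(50, 0.1, 1)), 360)
  for (w in c(3, 5, 9))
    expect_equal(as.numeric(median_filter(mono, w)), as.numeric(mono))

  x <- ecg_signal(rnorm(100), 360)
  expect_identical(median_filter(x, 1), x)
  expect_error(median_filter(x, 4), "odd")
  expect_error(median_filter(x, 101), "exceeds")

  # idempotent on piecewise-constant signals with long segments
  pc <- ecg_signal(rep(c(0, 3, -1, 2), each = 20), 360)
  once <- median_filter(pc, 5)
  expect_equal(as.numeric(median_filter(once, 5)), as.numeric(once))
})

test_that("notch removes the mains tone and spares the passband", {
  fs_hz <- 360
  t <- (0:(20 * fs_hz - 1)) / fs_hz
  tone50 <- ecg_signal(sin(2 * pi * 50 * t), fs_hz)
  out50 <- notch_filter(tone50, mains = 50)
  expect_lt(fft_amplitude(as.numeric(out50), fs_hz, 50), 0.1)

  tone10 <- ecg_signal(sin(2 * pi * 10 * t), fs_hz)
  out10 <- notch_filter(tone10, mains = 50)
  expect_lt(abs(fft_amplitude(as.numeric(out10), fs_hz, 10) - 1), 0.05)

  z <- ecg_signal(rep(0, 1000), fs_hz)
  expect_equal(as.numeric(notch_filter(z, 50)), rep(0, 1000))
  expect_error(notch_filter(tone10, mains = 200), "Nyquist")
})

test_that("band-pass and notch are linear in the input", {
  g <- generate_ecg(synth_config(duration = 5, seed = 17))
  x <- g$signal
  ax <- ecg_signal(3.7 * as.numeric(x), fs(x))
  expect_equal(3.7 * as.numeric(bandpass_filter(x)),
               as.numeric(bandpass_filter(ax)), tolerance = 1e-10)
  expect_equal(3.7 * as.numeric(notch_filter(x, 50)),
               as.numeric(notch_filter(ax, 50)), tolerance = 1e-10)
})

test_that("preprocess_signal applies configurable stage order", {
  g <- generate_ecg(synth_config(duration = 5, seed = 2))
  a <- preprocess_signal(g$signal)
  b <- notch_filter(bandpass_filter(median_filter(g$signal, 3)), 50)
  expect_equal(as.numeric(a), as.numeric(b))
  c2 <- preprocess_signal(g$signal, stages = c("bandpass", "median", "notch"))
  expect_false(isTRUE(all.equal(as.numeric(a), as.numeric(c2))))
  expect_error(preprocess_signal(g$signal, stages = c("median", "median")),
               "distinct")
})
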