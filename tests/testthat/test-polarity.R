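test_that("well-separated plateaus are recovered as clusters", {
  lens <- c(100, 200, 300, 400, 500)
  x <- ecg_signal(rep(c(0, 10, 20, 30, 40), times = lens), 360)
  cl <- cluster_amplitudes(x, k = 5, seed = 1)
  expect_identical(sort(cl$sizes), as.integer(lens))
  expect_equal(sort(cl$centroids), c(0, 10, 20, 30, 40), tolerance = 1e-8)
  expect_equal(sum(cl$sizes), length(x))
})

test_that("two-level square wave gives exact 2-means centroids", {
  x <- ecg_signal(rep(c(-2, 6), times = 50), 360)
  cl <- cluster_amplitudes(x, k = 2, seed = 7)
  expect_equal(sort(cl$centroids), c(-2, 6), tolerance = 1e-8)
  expect_error(cluster_amplitudes(x, k = 1), ">= 2")
})

test_that("clustering is deterministic given its seed", {
  g <- generate_ecg(synth_config(duration = 5, seed = 30))
  c1 <- cluster_amplitudes(g$signal, seed = 42)
  c2 <- cluster_amplitudes(g$signal, seed = 42)
  expect_identical(c1$labels, c2$labels)
  expect_identical(c1$centroids, c2$centroids)
})

test_that("degenerate amplitude sets are rejected", {
  expect_error(cluster_amplitudes(ecg_signal(rep(c(1, 2), 50), 360), k = 5),
               "degenerate")
  expect_error(assess_polarity(ecg_signal(rep(1, 100), 360),
                               structure(list(labels = rep(1L, 100),
                                              centroids = 1),
                                         class = "ecg_clusters")),
               "degenerate|constant")
})

test_that("1-D 2-means matches the brute-force optimal threshold partition", {
  set.seed(13)
  x <- c(rnorm(60, -4, 0.3), rnorm(40, 3, 0.3))
  cl <- cluster_amplitudes(ecg_signal(x, 360), k = 2, seed = 3)

  # oracle: exhaustive scan over all threshold partitions of sorted x
  xs <- sort(x)
  best <- Inf; best_t <- NA
  for (i in 1:(length(xs) - 1)) {
    l <- xs[1:i]; r <- xs[(i + 1):length(xs)]
    w <- sum((l - mean(l))^2) + sum((r - mean(r))^2)
    if (w < best) { best <- w; best_t <- i }
  }
  oracle_centroids <- sort(c(mean(xs[1:best_t]), mean(xs[(best_t + 1):length(xs)])))
  expect_equal(sort(cl$centroids), oracle_centroids, tolerance = 1e-6)
})

test_that("polarity verdict flips under negation with reciprocal evidence", {
  g <- generate_ecg(clean_config(duration = 10, seed = 41))
  cl <- cluster_amplitudes(g$signal, seed = 42)
  v <- assess_polarity(g$signal, cl)
  expect_identical(v$verdict, "normal")

  # the mirrored model is a valid fit for the negated signal
  neg <- ecg_signal(-as.numeric(g$signal), fs(g$signal))
  cl_neg <- cl
  cl_neg$centroids <- -cl$centroids
  v_neg <- assess_polarity(neg, cl_neg)
  expect_identical(v_neg$verdict, "inverted")
  expect_equal(v_neg$ratio, 1 / v$ratio, tolerance = 1e-12)

  # refitting from scratch reaches the same verdict
  v_refit <- assess_polarity(neg, cluster_amplitudes(neg, seed = 42))
  expect_identical(v_refit$verdict, "inverted")
})

test_that("polarity correction negates iff inverted and is an involution", {
  x <- generate_ecg(synth_config(duration = 4, seed = 2))$signal
  inv <- structure(list(verdict = "inverted", ratio = 2),
                   class = "polarity_verdict")
  nor <- structure(list(verdict = "normal", ratio = 0.5),
                   class = "polarity_verdict")
  expect_equal(as.numeric(correct_polarity(x, inv)), -as.numeric(x))
  expect_identical(correct_polarity(x, nor), x)
  expect_equal(as.numeric(correct_polarity(correct_polarity(x, inv), inv)),
               as.numeric(x))
})

test_that("k-means objective does not increase when iterations continue", {
  g <- generate_ecg(synth_config(duration = 5, seed = 19))
  w <- vapply(c(1, 3, 10, 300), function(it)
    cluster_amplitudes(g$signal, k = 5, seed = 42, max_iter = it)$tot_withinss,
    numeric(1))
  expect_true(all(diff(w) <= 1e-9))
})

test_that("an inverted record yields the same fiducials after correction", {
  cfg <- synth_config(duration = 12, seed = 55)
  plain <- generate_ecg(cfg)
  flipped <- generate_ecg(synth_config(duration = 12, seed = 55,
                                       inverted = TRUE))
  run <- function(sig) {
    f <- preprocess_signal(sig)
    fx <- fix_polarity(f)
    suppressWarnings(detect_fiducials(fx$signal, detect_r_peaks(fx$signal)))
  }
  f1 <- run(plain$signal)
  f2 <- run(flipped$signal)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  # corrected R peaks are positive deflections
  expect_true(all(as.numeric(preprocess_signal(plain$signal))[f1$R_Peaks + 1] > 0))
})
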