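#' Beat morphology template
#'
#' One cardiac cycle is modelled as a sum of Gaussian bumps, one per
#' wave. Amplitudes are signed (Q and S are troughs), widths are the
#' Gaussian standard deviations in seconds, and centers are offsets in
#' seconds relative to the R peak (negative = before R). Defaults give a
#' conventional lead-II-like morphology: R is the global per-beat
#' extremum and T exceeds P in amplitude.
#'
#' At short cycle lengths the T-wave offset and width are rate-adapted
#' during rendering (see [generate_ecg()]), mirroring the physiological
#' shortening and narrowing of the QT interval with heart rate.
#'
#' @param amplitude named numeric vector of signed wave amplitudes
#'   (a.u.) for P, Q, R, S, T.
#' @param width named numeric vector of Gaussian widths (s), all > 0.
#' @param center named numeric vector of wave-center offsets relative
#'   to R (s); must satisfy P < Q < 0 = R < S < T.
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(
    amplitude = c(P = 0.20, Q = -0.10, R = 1.00, S = -0.25, T = 0.25),
    width     = c(P = 0.025, Q = 0.010, R = 0.012, S = 0.010, T = 0.045),
    center    = c(P = -0.19, Q = -0.035, R = 0.000, S = 0.035, T = 0.19)) {
  waves <- c("P", "Q", "R", "S", "T")
  for (v in list(amplitude, width, center))
    if (!all(waves %in% names(v))) stopf("template vectors need names P,Q,R,S,T")
  amplitude <- amplitude[waves]; width <- width[waves]; center <- center[waves]
  if (any(width <= 0)) stopf("wave widths must be positive")
  if (!(amplitude[["Q"]] < 0 && amplitude[["S"]] < 0))
    stopf("Q and S amplitudes must be negative")
  if (!(amplitude[["P"]] > 0 && amplitude[["R"]] > 0 && amplitude[["T"]] > 0))
    stopf("P, R, T amplitudes must be positive")
  if (center[["R"]] != 0) stopf("R center must be 0 (offsets are relative to R)")
  if (!(center[["P"]] < center[["Q"]] && center[["Q"]] < 0 &&
        0 < center[["S"]] && center[["S"]] < center[["T"]]))
    stopf("centers must be ordered P < Q < 0 = R < S < T")
  structure(list(amplitude = amplitude, width = width, center = center),
            class = "beat_template")
}

#' Synthetic-ECG configuration
#'
#' Conditions for the synthetic generator: sampling, rhythm, and the
#' four contamination sources the preprocessing stages target (white
#' noise, baseline wander, mains interference, isolated impulses), plus
#' optional global polarity inversion.
#'
#' @param fs sampling frequency, Hz (default 360).
#' @param duration recording length, s.
#' @param heart_rate mean rate, bpm; must lie in \[20, 250\].
#' @param white_sd white-noise standard deviation (a.u.).
#' @param wander_amp,wander_freq baseline-wander amplitude (a.u.) and
#'   frequency (Hz), modelling respiration/electrode drift.
#' @param mains_amp,mains_freq powerline interference amplitude (a.u.)
#'   and frequency; `mains_freq` must be 50 or 60.
#' @param impulse_rate,impulse_amp rate (events/s) and amplitude (a.u.)
#'   of isolated single-sample spikes (Poisson-thinned), the artifact
#'   class the median stage removes.
#' @param inverted if `TRUE` the whole record is sign-flipped (swapped
#'   leads); with the same seed the result is the exact sample-wise
#'   negation of the non-inverted record.
#' @param jitter beat-to-beat uniform jitter on the RR interval as a
#'   fraction of the period (default 0.02, i.e. +/-2%); 0 disables it.
#' @param seed integer seed; every random draw in the generator is a
#'   pure function of (config, seed).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(fs = 360, duration = 30, heart_rate = 60,
                         white_sd = 0.03, wander_amp = 0.1, wander_freq = 0.25,
                         mains_amp = 0.02, mains_freq = 50,
                         impulse_rate = 0.5, impulse_amp = 0.5,
                         inverted = FALSE, jitter = 0.02, seed = 1L) {
  check_number(fs, "fs"); check_number(duration, "duration")
  if (fs <= 0) stopf("'fs' must be positive")
  if (duration <= 0) stopf("'duration' must be positive")
  check_number(heart_rate, "heart_rate", 20, 250)
  for (nm in c("white_sd", "wander_amp", "wander_freq", "mains_amp",
               "impulse_rate", "impulse_amp", "jitter")) {
    v <- get(nm)
    check_number(v, nm)
    if (v < 0) stopf("'%s' must be >= 0", nm)
  }
  if (!mains_freq %in% c(50, 60)) stopf("'mains_freq' must be 50 or 60 Hz")
  structure(list(fs = fs, duration = duration, heart_rate = heart_rate,
                 white_sd = white_sd, wander_amp = wander_amp,
                 wander_freq = wander_freq, mains_amp = mains_amp,
                 mains_freq = mains_freq, impulse_rate = impulse_rate,
                 impulse_amp = impulse_amp, inverted = isTRUE(inverted),
                 jitter = jitter, seed = as.integer(seed)),
            class = "synth_config")
}

# T-peak offset adapted to the cycle length so that the T of one beat
# stays clear of the P-search window of the next (QT rate adaptation);
# the T width shrinks proportionally so its tail stays clear too
adapt_t_center <- function(t_center, s_center, s_width, period) {
  t_adj <- min(t_center, period - 0.30)
  max(t_adj, s_center + 2 * s_width + 0.01)
}

#' Generate a synthetic multi-beat ECG with known fiducials
#'
#' Renders a seeded, reproducible single-lead ECG: a train of
#' sum-of-Gaussian beats (see [beat_template()]) at the configured heart
#' rate with optional RR jitter, plus baseline wander, mains
#' interference, white noise and isolated impulses. The true sample
#' index of every wave peak/trough of every fully contained beat is
#' returned as ground truth, so downstream detection stages can be
#' scored exactly.
#'
#' Wave centers are snapped to the sample grid, so with all noise levels
#' at zero the true R index of each beat is exactly the argmax of the
#' rendered samples. With `inverted = TRUE` the returned signal is the
#' sample-wise negation of the `inverted = FALSE` signal for the same
#' seed; ground-truth indices are unchanged.
#'
#' @param config a [synth_config()].
#' @param template a [beat_template()].
#' @return A list with elements `signal` (an [ecg_signal()]), `truth`
#'   (a [fiducial_table()] of 0-based true indices, one row per beat)
#'   and `inverted` (logical flag copied from the config).
#' @examples
#' g <- generate_ecg(synth_config(duration = 10, seed = 7))
#' nrow(g$truth)
#' @export
generate_ecg <- function(config = synth_config(), template = beat_template()) {
  stopifnot(inherits(config, "synth_config"), inherits(template, "beat_template"))
  fs <- config$fs
  n <- round(fs * config$duration)
  period <- 60 / config$heart_rate
  cen <- template$center
  wid <- template$width
  cen[["T"]] <- adapt_t_center(cen[["T"]], cen[["S"]], wid[["S"]], period)
  wid[["T"]] <- wid[["T"]] * cen[["T"]] / template$center[["T"]]
  margin <- max(abs(cen)) + 0.12   # keep every wave window inside the record

  with_seed(config$seed, {
    # R-peak times with uniform RR jitter
    r_times <- numeric(0)
    t_cur <- margin
    while (t_cur <= config$duration - margin) {
      r_times <- c(r_times, t_cur)
      t_cur <- t_cur + period * (1 + config$jitter * runif(1, -1, 1))
    }
    if (length(r_times) == 0L)
      stopf("duration %.3g s too short for one full beat at %g bpm",
            config$duration, config$heart_rate)

    x <- numeric(n)
    r_idx <- round(r_times * fs)                  # 0-based
    truth <- matrix(0L, nrow = length(r_idx), ncol = 5L,
                    dimnames = list(NULL, c("P", "Q", "R", "S", "T")))
    for (w in c("P", "Q", "R", "S", "T")) {
      off <- round(cen[[w]] * fs)
      wc <- r_idx + off                            # 0-based wave centers
      truth[, w] <- as.integer(wc)
      sig_w <- wid[[w]] * fs
      half <- ceiling(6 * sig_w)
      for (c0 in wc) {
        lo <- max(0L, c0 - half); hi <- min(n - 1L, c0 + half)
        i <- lo:hi
        x[i + 1L] <- x[i + 1L] +
          template$amplitude[[w]] * exp(-0.5 * ((i - c0) / sig_w)^2)
      }
    }

    tt <- (seq_len(n) - 1) / fs
    if (config$wander_amp > 0)
      x <- x + config$wander_amp *
        sin(2 * pi * config$wander_freq * tt + runif(1, 0, 2 * pi))
    if (config$mains_amp > 0)
      x <- x + config$mains_amp *
        sin(2 * pi * config$mains_freq * tt + runif(1, 0, 2 * pi))
    if (config$white_sd > 0) x <- x + rnorm(n, 0, config$white_sd)
    if (config$impulse_rate > 0) {
      k <- rpois(1, config$impulse_rate * config$duration)
      if (k > 0) {
        pos <- sample.int(n, min(k, n))
        x[pos] <- x[pos] + sample(c(-1, 1), length(pos), replace = TRUE) *
          config$impulse_amp * runif(length(pos), 0.8, 1.2)
      }
    }
    if (config$inverted) x <- -x

    tab <- fiducial_table(data.frame(
      Q_Points = truth[, "Q"], R_Peaks = truth[, "R"],
      S_Points = truth[, "S"], T_Points = truth[, "T"],
      P_Points = truth[, "P"]), signal_length = n)
    list(signal = ecg_signal(x, fs), truth = tab, inverted = config$inverted)
  })
}
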