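#' Band-pass filter specification
#'
#' Cut-off frequencies, order and sampling rate for the software
#' band-pass stage. Defaults follow the conventional ECG passband:
#' 0.5 Hz low cut (removes baseline wander and other sub-cardiac
#' drift), 100 Hz high cut (suppresses high-frequency noise), order 2,
#' 360 Hz sampling.
#'
#' @param f_lo low cut-off (Hz), `0 < f_lo < f_hi`.
#' @param f_hi high cut-off (Hz), must be below the Nyquist rate
#'   `fs / 2`.
#' @param order filter order, a positive integer.
#' @param fs sampling frequency (Hz).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(f_lo = 0.5, f_hi = 100, order = 2, fs = 360) {
  check_number(f_lo, "f_lo"); check_number(f_hi, "f_hi")
  check_number(order, "order"); check_number(fs, "fs")
  if (order < 1 || order != floor(order)) stopf("'order' must be a positive integer")
  if (f_lo <= 0) stopf("'f_lo' must be positive")
  if (f_hi <= f_lo) stopf("'f_hi' must exceed 'f_lo'")
  if (f_hi >= fs / 2)
    stopf("'f_hi' (%g Hz) must be below the Nyquist frequency fs/2 = %g Hz",
          f_hi, fs / 2)
  structure(list(f_lo = f_lo, f_hi = f_hi, order = as.integer(order), fs = fs),
            class = "filter_spec")
}

#' Analytic magnitude response
#'
#' The magnitude-response model of the band-pass stage,
#' `H(f) = 1 / (1 + (f / fc)^(2 n))`: monotone decreasing in `f`,
#' equal to 1 at DC and to exactly 1/2 at the cut-off `f = fc` for
#' every order `n`; larger `n` sharpens the transition around `fc`.
#'
#' @param f frequency (Hz), vectorised, `f >= 0`.
#' @param fc cut-off frequency (Hz), positive.
#' @param n response order, `n >= 1`.
#' @return Dimensionless gain in `(0, 1]`.
#' @examples
#' response_magnitude(50, 50, 2)   # 0.5 at the cut-off
#' @export
response_magnitude <- function(f, fc, n = 2) {
  if (!is.numeric(f) || any(f < 0)) stopf("'f' must be >= 0")
  check_number(fc, "fc"); check_number(n, "n")
  if (fc <= 0) stopf("'fc' must be positive")
  if (n < 1) stopf("'n' must be >= 1")
  1 / (1 + (f / fc)^(2 * n))
}

#' Zero-phase Butterworth band-pass
#'
#' Applies an order-`order` Butterworth band-pass forward and backward
#' (`signal::filtfilt`), so the effective magnitude response is the
#' squared Butterworth response and the phase is zero -- fiducial
#' timing is not skewed by the filter.
#'
#' @param signal an [ecg_signal()].
#' @param spec a [filter_spec()]; its `fs` must match the signal.
#' @return The filtered [ecg_signal()], same length as the input.
#' @export
bandpass_filter <- function(signal, spec = filter_spec(fs = fs(signal))) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(spec, "filter_spec"))
  if (spec$fs != fs(signal))
    stopf("filter fs (%g) does not match signal fs (%g)", spec$fs, fs(signal))
  if (length(signal) <= 3 * spec$order)
    stopf("signal too short for an order-%d filter", spec$order)
  b <- signal::butter(spec$order, c(spec$f_lo, spec$f_hi) / (spec$fs / 2),
                      type = "pass")
  reclass_signal(signal::filtfilt(b, as.numeric(signal)), signal)
}

#' Running-median filter
#'
#' Median smoothing aimed at impulsive artifacts: each sample is
#' replaced by the median of the centred odd-length window. Boundaries
#' are handled by edge replication. A window of 1 is the identity.
#'
#' @param signal an [ecg_signal()].
#' @param window odd positive window length in samples (default 3).
#' @return The filtered [ecg_signal()], same length as the input.
#' @examples
#' median_filter(ecg_signal(c(0, 0, 5, 0, 0), 360), window = 3)
#' @export
median_filter <- function(signal, window = 3) {
  stopifnot(inherits(signal, "ecg_signal"))
  check_number(window, "window")
  if (window != floor(window) || window < 1) stopf("'window' must be a positive integer")
  if (window %% 2 == 0) stopf("'window' must be odd, got %d", window)
  if (window > length(signal)) stopf("'window' exceeds the signal length")
  if (window == 1) return(signal)
  x <- as.numeric(signal)
  h <- (window - 1) / 2
  padded <- c(rep(x[1], h), x, rep(x[length(x)], h))
  y <- runmed(padded, window, endrule = "keep")
  reclass_signal(y[(h + 1):(h + length(x))], signal)
}

#' Mains notch filter
#'
#' Zero-phase Butterworth band-stop centred on the powerline frequency
#' (50 or 60 Hz), removing narrowband AC interference while leaving
#' the rest of the passband essentially untouched.
#'
#' @param signal an [ecg_signal()].
#' @param mains powerline frequency (Hz), typically 50 or 60; must be
#'   below `fs / 2`.
#' @param bandwidth stop-band width (Hz), default 4 (mains +/- 2 Hz).
#' @param order Butterworth order of the stop-band prototype.
#' @return The filtered [ecg_signal()], same length as the input.
#' @export
notch_filter <- function(signal, mains = 50, bandwidth = 4, order = 2) {
  stopifnot(inherits(signal, "ecg_signal"))
  check_number(mains, "mains"); check_number(bandwidth, "bandwidth")
  f <- fs(signal)
  if (mains <= 0) stopf("'mains' must be positive")
  if (mains >= f / 2)
    stopf("'mains' (%g Hz) must be below the Nyquist frequency fs/2 = %g Hz",
          mains, f / 2)
  lo <- mains - bandwidth / 2
  hi <- mains + bandwidth / 2
  if (lo <= 0 || hi >= f / 2) stopf("stop band [%g, %g] Hz out of range", lo, hi)
  b <- signal::butter(order, c(lo, hi) / (f / 2), type = "stop")
  reclass_signal(signal::filtfilt(b, as.numeric(signal)), signal)
}

#' Full noise-suppression chain
#'
#' Runs the software filtering stages in the default order
#' median -> band-pass -> notch. The order is configurable through
#' `stages`; each stage appears at most once.
#'
#' @param signal an [ecg_signal()].
#' @param median_window window for [median_filter()] (odd, samples).
#' @param spec a [filter_spec()] for the band-pass.
#' @param mains powerline frequency for [notch_filter()]; `NULL` skips
#'   the notch.
#' @param stages character vector giving the stage order.
#' @return The filtered [ecg_signal()].
#' @export
preprocess_signal <- function(signal, median_window = 3,
                              spec = filter_spec(fs = fs(signal)),
                              mains = 50,
                              stages = c("median", "bandpass", "notch")) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (anyDuplicated(stages) || !all(stages %in% c("median", "bandpass", "notch")))
    stopf("'stages' must be distinct values among median, bandpass, notch")
  for (st in stages) {
    signal <- switch(st,
      median   = median_filter(signal, median_window),
      bandpass = bandpass_filter(signal, spec),
      notch    = if (is.null(mains)) signal else notch_filter(signal, mains))
  }
  signal
}
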