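#' ECG signal container
#'
#' A single-lead ECG is stored as a numeric amplitude series (arbitrary
#' units) with its sampling frequency attached. All filtering and
#' detection functions in the package accept and return this class.
#'
#' Sample *indices* reported by the package (R peaks, fiducial tables,
#' ground truth) are 0-based: index `i` refers to `signal[[i + 1]]`. This
#' matches the convention of the CSV schemas, whose index column starts
#' at 0.
#'
#' @param x numeric vector of amplitudes; must be finite.
#' @param fs sampling frequency in Hz (positive).
#' @return An object of class `ecg_signal`: a numeric vector with an
#'   `fs` attribute.
#' @examples
#' s <- ecg_signal(sin(2 * pi * 1 * seq(0, 2, by = 1 / 360)), fs = 360)
#' fs(s)
#' @export
ecg_signal <- function(x, fs) {
  if (!is.numeric(x) || length(x) == 0L)
    stopf("'x' must be a non-empty numeric vector")
  if (anyNA(x) || any(!is.finite(x)))
    stopf("ECG samples must be finite (non-finite value at sample %d)",
          which(!is.finite(x))[1L])
  check_number(fs, "fs")
  if (fs <= 0) stopf("'fs' must be positive")
  structure(as.numeric(x), fs = as.numeric(fs), class = "ecg_signal")
}

#' Sampling frequency of an ECG signal
#' @param x an `ecg_signal`.
#' @return Sampling frequency in Hz.
#' @export
fs <- function(x) {
  v <- attr(x, "fs")
  if (is.null(v)) stopf("object has no sampling frequency; use ecg_signal()")
  v
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.2f s), range [%.4g, %.4g]\n",
              length(x), fs(x), length(x) / fs(x), min(x), max(x)))
  invisible(x)
}

#' @export
plot.ecg_signal <- function(x, ...) {
  t <- (seq_along(x) - 1) / fs(x)
  plot(t, as.numeric(x), type = "l", xlab = "time (s)",
       ylab = "amplitude (a.u.)", ...)
  invisible(x)
}

# rebuild an ecg_signal after a numeric transformation
reclass_signal <- function(x, template) ecg_signal(as.numeric(x), fs(template))

as_signal <- function(x, fs_arg = NULL) {
  if (inherits(x, "ecg_signal")) return(x)
  if (is.null(fs_arg)) stopf("'fs' required for a plain numeric signal")
  ecg_signal(x, fs_arg)
}
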