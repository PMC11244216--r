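#' Per-beat fiducial table
#'
#' Validating constructor for the per-beat fiducial schema: integer
#' 0-based sample indices with columns `Q_Points`, `R_Peaks`,
#' `S_Points`, `T_Points`, `P_Points`. Every row must satisfy
#' P < Q < R < S < T and R indices must be strictly increasing across
#' rows.
#'
#' @param df data frame holding the five fiducial columns (extra
#'   columns are preserved).
#' @param signal_length optional signal length; when given, all indices
#'   must lie in `[0, signal_length)`.
#' @return `df` with class `fiducial_table` prepended.
#' @export
fiducial_table <- function(df, signal_length = NULL) {
  need <- fiducial_columns()
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("fiducial table is missing column(s): %s", paste(miss, collapse = ", "))
  for (cn in need) {
    v <- df[[cn]]
    if (!is.numeric(v) || anyNA(v)) stopf("column '%s' must be numeric without NA", cn)
    if (any(v != floor(v))) stopf("column '%s' must hold integer sample indices", cn)
    if (any(v < 0)) stopf("column '%s' has negative sample indices", cn)
    df[[cn]] <- as.integer(v)
  }
  bad <- which(!(df$P_Points < df$Q_Points & df$Q_Points < df$R_Peaks &
                 df$R_Peaks < df$S_Points & df$S_Points < df$T_Points))
  if (length(bad))
    stopf("ordering P < Q < R < S < T violated in row(s): %s",
          paste(bad, collapse = ", "))
  if (nrow(df) > 1L && any(diff(df$R_Peaks) <= 0))
    stopf("R_Peaks must be strictly increasing across rows")
  if (!is.null(signal_length) && nrow(df) > 0L &&
      max(df$T_Points) >= signal_length)
    stopf("fiducial indices exceed signal length %d", signal_length)
  class(df) <- unique(c("fiducial_table", class(df)))
  df
}

fiducial_columns <- function()
  c("Q_Points", "R_Peaks", "S_Points", "T_Points", "P_Points")

#' Delineation window lengths
#'
#' Search windows for the window-based fiducial delineation, in
#' seconds: the Q trough is sought within `q_win` before the R peak,
#' the S trough within `s_win` after it, the T peak within `t_win`
#' after S, and the P peak between `p_win_far` and `p_win_near` before
#' Q. Fractional sample counts (e.g. 14.4 samples for 0.04 s at
#' 360 Hz) are floored when windows are materialised.
#'
#' @param q_win,s_win,t_win,p_win_near,p_win_far window durations (s).
#' @param fs sampling frequency (Hz).
#' @return An object of class `fiducial_windows`.
#' @export
fiducial_windows <- function(q_win = 0.04, s_win = 0.08, t_win = 0.2,
                             p_win_near = 0.12, p_win_far = 0.20, fs = 360) {
  for (nm in c("q_win", "s_win", "t_win", "p_win_near", "p_win_far")) {
    v <- check_number(get(nm), nm)
    if (v <= 0) stopf("'%s' must be positive", nm)
  }
  check_number(fs, "fs")
  if (fs <= 0) stopf("'fs' must be positive")
  if (p_win_far <= p_win_near) stopf("'p_win_far' must exceed 'p_win_near'")
  period_250 <- 60 / 250
  if (max(q_win, s_win, t_win, p_win_far) > period_250)
    stopf("windows must be shorter than one beat period at 250 bpm (%.3g s)",
          period_250)
  structure(list(q_win = q_win, s_win = s_win, t_win = t_win,
                 p_win_near = p_win_near, p_win_far = p_win_far, fs = fs),
            class = "fiducial_windows")
}

#' Window duration in samples
#'
#' Converts a window duration to a (real, pre-rounding) sample count:
#' `duration * fs`. At 360 Hz the canonical delineation windows give
#' 14.4 (0.04 s), 28.8 (0.08 s) and 72 (0.2 s) samples. Integer window
#' lengths are the floor of this value.
#'
#' @param duration window duration (s).
#' @param fs sampling frequency (Hz).
#' @return `duration * fs`, unrounded.
#' @export
window_samples <- function(duration, fs) {
  if (any(duration <= 0) || any(fs <= 0)) stopf("duration and fs must be positive")
  duration * fs
}

#' Detect R peaks
#'
#' Simple deterministic R-peak detector for polarity-corrected,
#' band-passed signals: candidate peaks are local maxima exceeding an
#' adaptive threshold (`threshold_factor` times the rolling 95th
#' percentile of the signal, window +/-1 s), then a refractory rule
#' enforces a minimum RR spacing, keeping the larger peak (ties: the
#' earlier index).
#'
#' @param signal an [ecg_signal()] (filtered, normal polarity).
#' @param min_rr refractory period in seconds (default 0.2).
#' @param threshold_factor multiplier on the rolling 95th percentile
#'   (default 1.2).
#' @return Strictly increasing integer vector of 0-based R-peak sample
#'   indices; empty when the signal is shorter than `min_rr * fs` or no
#'   sample exceeds the threshold.
#' @export
detect_r_peaks <- function(signal, min_rr = 0.2, threshold_factor = 1.2) {
  stopifnot(inherits(signal, "ecg_signal"))
  check_number(min_rr, "min_rr"); check_number(threshold_factor, "threshold_factor")
  if (min_rr <= 0 || threshold_factor <= 0)
    stopf("'min_rr' and 'threshold_factor' must be positive")
  x <- as.numeric(signal); n <- length(x); f <- fs(signal)
  if (n < min_rr * f) return(integer(0))

  # rolling 95th percentile, evaluated on a half-second grid
  w <- round(f); step <- max(1L, round(f / 2))
  centers <- unique(c(seq(1L, n, by = step), n))
  q <- vapply(centers, function(i)
    quantile(x[max(1L, i - w):min(n, i + w)], 0.95, names = FALSE), numeric(1))
  thr <- threshold_factor *
    approx(centers, q, xout = seq_len(n), rule = 2)$y

  i <- 2:(n - 1L)
  cand <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L] & x[i] > thr[i]]
  if (!length(cand)) return(integer(0))

  # refractory: keep larger peaks first, ties broken by earlier index
  ord <- cand[order(-x[cand], cand)]
  keep <- integer(0)
  gap <- min_rr * f
  for (p in ord)
    if (!length(keep) || all(abs(keep - p) >= gap)) keep <- c(keep, p)
  as.integer(sort(keep) - 1L)
}

#' Delineate P, Q, S and T around detected R peaks
#'
#' For each R peak, the Q trough is the argmin over `[R - q_win, R)`,
#' the S trough the argmin over `(R, R + s_win]`, the T peak the argmax
#' over `(S, S + t_win]` and the P peak the argmax over
#' `[Q - p_win_far, Q - p_win_near]` (all windows floored to whole
#' samples; ties resolved to the first extremum). Beats whose windows
#' would leave the signal, or whose windows would run into the next
#' beat's R peak, are dropped with a warning; the dropped count is kept
#' in the `dropped_beats` attribute.
#'
#' @param signal an [ecg_signal()].
#' @param r_peaks 0-based R-peak indices from [detect_r_peaks()] on the
#'   same signal.
#' @param windows a [fiducial_windows()]; its `fs` must match the
#'   signal.
#' @return A [fiducial_table()] with one row per retained beat.
#' @export
detect_fiducials <- function(signal, r_peaks,
                             windows = fiducial_windows(fs = fs(signal))) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(windows, "fiducial_windows"))
  if (windows$fs != fs(signal))
    stopf("windows fs (%g) does not match signal fs (%g)", windows$fs, fs(signal))
  x <- as.numeric(signal); n <- length(x); f <- fs(signal)
  qn <- floor(window_samples(windows$q_win, f))
  sn <- floor(window_samples(windows$s_win, f))
  tn <- floor(window_samples(windows$t_win, f))
  p_near <- floor(window_samples(windows$p_win_near, f))
  p_far  <- floor(window_samples(windows$p_win_far, f))

  empty <- fiducial_table(data.frame(
    Q_Points = integer(0), R_Peaks = integer(0), S_Points = integer(0),
    T_Points = integer(0), P_Points = integer(0)))
  if (!length(r_peaks)) return(empty)
  r_peaks <- sort(as.integer(r_peaks))
  if (any(r_peaks < 0 | r_peaks >= n)) stopf("r_peaks outside the signal")

  rows <- vector("list", length(r_peaks))
  dropped <- 0L
  for (b in seq_along(r_peaks)) {
    r1 <- r_peaks[b] + 1L                       # 1-based position of R
    nxt <- if (b < length(r_peaks)) r_peaks[b + 1L] + 1L else Inf
    # fail closed on boundary or tachycardic window overlap
    if (r1 - qn < 1L || r1 + sn + tn > n || r1 - qn - p_far < 1L ||
        r1 + sn + tn >= nxt) {
      dropped <- dropped + 1L
      next
    }
    qwin <- (r1 - qn):(r1 - 1L)
    q1 <- qwin[which.min(x[qwin])]
    swin <- (r1 + 1L):(r1 + sn)
    s1 <- swin[which.min(x[swin])]
    twin <- (s1 + 1L):(s1 + tn)
    t1 <- twin[which.max(x[twin])]
    pwin <- (q1 - p_far):(q1 - p_near)
    p1 <- pwin[which.max(x[pwin])]
    rows[[b]] <- c(Q = q1, R = r1, S = s1, T = t1, P = p1) - 1L
  }
  if (dropped)
    warning(sprintf("%d beat(s) dropped: search windows outside the signal or overlapping the next beat", dropped))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    attr(empty, "dropped_beats") <- dropped
    return(empty)
  }
  m <- do.call(rbind, rows)
  out <- fiducial_table(data.frame(
    Q_Points = m[, "Q"], R_Peaks = m[, "R"], S_Points = m[, "S"],
    T_Points = m[, "T"], P_Points = m[, "P"]), signal_length = n)
  attr(out, "dropped_beats") <- dropped
  out
}
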