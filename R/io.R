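#' Write / read an ECG signal as CSV
#'
#' Signals are stored as a two-column CSV `sample_index,amplitude`
#' (0-based index) with a YAML sidecar `<path>.meta.yaml` holding the
#' sampling frequency, so a record round-trips without extra
#' arguments.
#'
#' @param signal an [ecg_signal()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "ecg_signal"))
  df <- data.frame(sample_index = seq_along(signal) - 1L,
                   amplitude = as.numeric(signal))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(fs = fs(signal)), paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_signal
#' @param fs sampling frequency in Hz; if `NULL`, taken from the YAML
#'   sidecar written by `write_signal`.
#' @details `read_signal` accepts the 1-column dialect (a single
#'   `amplitude` column) or the 2-column dialect
#'   (`sample_index,amplitude`; the index column is ignored for data).
#'   A header row is mandatory. Non-numeric or non-finite cells are a
#'   parse error naming the offending row.
#' @export
read_signal <- function(path, fs = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stopf("empty signal file: %s", path)
  col <- if ("amplitude" %in% names(df)) "amplitude" else names(df)[ncol(df)]
  v <- df[[col]]
  if (!is.numeric(v))
    stopf("non-numeric amplitude at data row %d of %s",
          which(is.na(suppressWarnings(as.numeric(v))))[1L], path)
  if (anyNA(v) || any(!is.finite(v)))
    stopf("non-finite amplitude at data row %d of %s",
          which(!is.finite(v))[1L], path)
  if (is.null(fs)) {
    sidecar <- paste0(path, ".meta.yaml")
    if (!file.exists(sidecar))
      stopf("no 'fs' given and no sidecar %s found", sidecar)
    fs <- yaml::read_yaml(sidecar)$fs
  }
  ecg_signal(v, fs)
}

#' Read / write fiducial tables in the labelled-beat CSV schema
#'
#' The schema has columns `Q_Points`, `R_Peaks`, `S_Points`,
#' `T_Points`, `P_Points` (an `Index` column is optional and ignored;
#' an `Anomaly` column, when present, is preserved). Unknown extra
#' columns produce a warning and are dropped. Rows violating the
#' per-beat ordering invariant are rejected with a report and removed.
#'
#' @param path CSV path.
#' @return For `read_fiducial_table`, a [fiducial_table()] (with
#'   `Anomaly` column when present in the file).
#' @export
read_fiducial_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, check.names = FALSE)
  miss <- setdiff(fiducial_columns(), names(df))
  if (length(miss))
    stopf("missing column(s) in %s: %s", path, paste(miss, collapse = ", "))
  known <- c("Index", fiducial_columns(), "Anomaly")
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warning(sprintf("ignoring unknown column(s): %s", paste(extra, collapse = ", ")))
  }
  df <- df[, intersect(c(fiducial_columns(), "Anomaly"), names(df)), drop = FALSE]
  ok <- with(df, P_Points < Q_Points & Q_Points < R_Peaks &
                 R_Peaks < S_Points & S_Points < T_Points)
  if (any(!ok)) {
    warning(sprintf("rejecting %d row(s) violating P<Q<R<S<T ordering: %s",
                    sum(!ok), paste(which(!ok), collapse = ", ")))
    df <- df[ok, , drop = FALSE]
    rownames(df) <- NULL
  }
  fiducial_table(df)
}

#' @rdname read_fiducial_table
#' @param table a [fiducial_table()] (optionally with `Anomaly`).
#' @export
write_fiducial_table <- function(table, path) {
  df <- as.data.frame(table)
  keep <- intersect(c(fiducial_columns(), "Anomaly"), names(df))
  out <- cbind(Index = seq_len(nrow(df)) - 1L, df[, keep, drop = FALSE])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write patient tables in the ten-column schema
#'
#' @param path CSV path.
#' @return For `read_patient_table`, a validated patient data frame.
#' @export
read_patient_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  validate_patient_table(read.csv(path, check.names = FALSE))
}

#' @rdname read_patient_table
#' @param table a patient table.
#' @export
write_patient_table <- function(table, path) {
  df <- validate_patient_table(table)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Minimal WFDB record reader
#'
#' Reads a waveform-database record (header `.hea` plus binary `.dat`)
#' for the common storage formats 16 (little-endian 16-bit) and 212
#' (packed 12-bit pairs). Stored ADC units are converted to physical
#' units via `(adc - baseline) / gain`.
#'
#' @param record path to the record without extension.
#' @param channel which signal channel to return (default 1).
#' @return An [ecg_signal()] with the header's sampling frequency.
#' @export
read_wfdb <- function(record, channel = 1) {
  hea <- paste0(record, ".hea")
  if (!file.exists(hea)) stopf("header not found: %s", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(hd[2])
  fs_rec <- as.numeric(hd[3] %||% "250")
  nsamp <- if (length(hd) >= 4) as.integer(hd[4]) else NA_integer_
  if (channel < 1 || channel > nsig) stopf("record has %d channel(s)", nsig)
  sig <- strsplit(trimws(lines[1 + seq_len(nsig)]), "\\s+")
  fname <- sig[[1]][1]
  fmt <- sub("x.*$", "", sig[[channel]][2])
  gain_field <- if (length(sig[[channel]]) >= 3) sig[[channel]][3] else "200"
  gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_field)))
  if (is.na(gain) || gain == 0) gain <- 200
  baseline <- if (grepl("\\(", gain_field))
    as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field)) else 0
  dat <- file.path(dirname(hea), fname)
  if (!file.exists(dat)) stopf("signal file not found: %s", dat)
  raw <- readBin(dat, "raw", n = file.info(dat)$size)
  adc <- switch(fmt,
    "16" = {
      v <- readBin(raw, "integer", n = length(raw) / 2, size = 2,
                   signed = TRUE, endian = "little")
      matrix(v, ncol = nsig, byrow = TRUE)[, channel]
    },
    "212" = {
      b <- as.integer(raw)
      ntrip <- length(b) %/% 3
      b1 <- b[seq(1, 3 * ntrip, by = 3)]
      b2 <- b[seq(2, 3 * ntrip, by = 3)]
      b3 <- b[seq(3, 3 * ntrip, by = 3)]
      s1 <- b1 + bitwAnd(b2, 15L) * 256L
      s2 <- b3 + bitwAnd(b2 %/% 16L, 15L) * 256L
      s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
      s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
      v <- as.vector(rbind(s1, s2))
      matrix(v, ncol = nsig, byrow = TRUE)[, channel]
    },
    stopf("unsupported WFDB format '%s' (formats 16 and 212 are supported)", fmt))
  if (!is.na(nsamp)) adc <- adc[seq_len(min(nsamp, length(adc)))]
  ecg_signal((adc - baseline) / gain, fs_rec)
}

# format-16 WFDB writer (single .dat shared by all channels); used for
# round-trip testing and small exports
write_wfdb <- function(signal, record, gain = 200, units = "mV") {
  stopifnot(inherits(signal, "ecg_signal"))
  adc <- as.integer(round(as.numeric(signal) * gain))
  if (any(abs(adc) > 32767)) stopf("signal exceeds 16-bit ADC range at gain %g", gain)
  base <- basename(record)
  writeLines(c(sprintf("%s 1 %g %d", base, fs(signal), length(adc)),
               sprintf("%s.dat 16 %g(0)/%s 16 0 %d 0 0 ECG",
                       base, gain, units, adc[1])),
             paste0(record, ".hea"))
  con <- file(paste0(record, ".dat"), "wb")
  on.exit(close(con))
  writeBin(adc, con, size = 2, endian = "little")
  invisible(record)
}
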