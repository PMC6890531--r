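# Delimited-text readers and writers for CSI records and sensor traces.
#
# CSI container: long-format CSV with header `time,antenna,subcarrier,real,
# imag`, one row per (packet, antenna, subcarrier). Sensor trace: CSV with
# header `time,value`. Both formats require a uniform sampling grid.

#' Write a CFR series to a delimited-text container
#'
#' @param series a [cfr_series()].
#' @param path output file path (CSV with header
#'   `time,antenna,subcarrier,real,imag`).
#' @return `path`, invisibly.
#' @export
write_csi <- function(series, path) {
  stopifnot(inherits(series, "cfr_series"))
  tt <- series$t0 + (seq_len(series$n_packets) - 1) / series$fs
  grid <- data.table::CJ(subcarrier = seq_len(series$n_subcarriers),
                         antenna = seq_len(series$n_antennas),
                         packet = seq_len(series$n_packets),
                         sorted = FALSE)
  v <- series$values[cbind(grid$packet, grid$antenna, grid$subcarrier)]
  dt <- data.table::data.table(
    time = tt[grid$packet], antenna = grid$antenna,
    subcarrier = grid$subcarrier, real = Re(v), imag = Im(v))
  data.table::setorder(dt, time, antenna, subcarrier)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a CFR series from a delimited-text container
#'
#' Validates the schema (all five columns present), a complete
#' packet x antenna x subcarrier grid (ragged files are rejected) and a
#' uniform packet timing grid (irregular timestamps are rejected rather
#' than resampled).
#'
#' @param path CSV file written by [write_csi()] or matching its schema.
#' @return a [cfr_series()].
#' @export
read_csi <- function(path) {
  dt <- data.table::fread(path)
  need <- c("time", "antenna", "subcarrier", "real", "imag")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("CSI file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  times <- sort(unique(dt$time))
  ants <- sort(unique(dt$antenna))
  subs <- sort(unique(dt$subcarrier))
  if (nrow(dt) != length(times) * length(ants) * length(subs))
    stop("ragged CSI file: incomplete packet x antenna x subcarrier grid")
  fs <- infer_fs(times, what = "CSI packet")
  data.table::setorder(dt, subcarrier, antenna, time)
  values <- array(complex(real = dt$real, imaginary = dt$imag),
                  dim = c(length(times), length(ants), length(subs)))
  cfr_series(values, fs = fs, t0 = times[1])
}

#' Write a sensor trace (`time,value` CSV)
#'
#' @param x numeric trace sampled uniformly at `fs`.
#' @param fs sampling rate in Hz.
#' @param path output file path.
#' @param t0 start time in seconds.
#' @return `path`, invisibly.
#' @export
write_sensor <- function(x, fs, path, t0 = 0) {
  dt <- data.table::data.table(
    time = t0 + (seq_along(x) - 1) / fs, value = x)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a sensor trace (`time,value` CSV)
#'
#' Checks that timestamps are strictly increasing and uniform; jittered or
#' non-monotonic time grids are rejected.
#'
#' @param path CSV file with header `time,value`.
#' @return list with `values` (numeric), `fs` (Hz), `t0` (s).
#' @export
read_sensor <- function(path) {
  dt <- data.table::fread(path)
  missing_cols <- setdiff(c("time", "value"), names(dt))
  if (length(missing_cols))
    stop("sensor file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.unsorted(dt$time, strictly = TRUE))
    stop("sensor timestamps must be strictly increasing")
  fs <- infer_fs(dt$time, what = "sensor sample")
  list(values = dt$value, fs = fs, t0 = dt$time[1])
}

# Detect the sampling rate from a timestamp vector, rejecting jitter beyond
# 1% of the sample period.
infer_fs <- function(times, what = "sample") {
  if (length(times) < 2) stop("need at least 2 ", what, "s")
  dts <- diff(times)
  dt0 <- median(dts)
  if (dt0 <= 0) stop(what, " timestamps must be increasing")
  if (max(abs(dts - dt0)) > 0.01 * dt0)
    stop("irregular ", what, " timing: timestamps deviate from a uniform ",
         "grid by more than 1% of the sample period")
  fs <- 1 / dt0
  # absorb text round-off for integer rates
  if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)
  fs
}
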