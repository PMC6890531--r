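#' Channel frequency response series
#'
#' Container for a time-ordered sequence of channel-frequency-response (CFR)
#' packets. Each packet holds the complex channel gain of every OFDM
#' subcarrier on every receive antenna; the packet stream, sampled at a fixed
#' rate, is the raw record from which breathing is sensed.
#'
#' @param values complex array of dimension `N x antennas x subcarriers`
#'   (packets x receive antennas x OFDM subcarriers). All entries must be
#'   finite.
#' @param fs sampling rate in Hz (packets per second), `> 0`.
#' @param t0 start time of the record in seconds.
#'
#' @return An object of class `cfr_series`: a list with elements `values`,
#'   `fs`, `t0`, `n_packets`, `n_antennas`, `n_subcarriers`.
#' @export
#' @examples
#' v <- array(complex(real = rnorm(50 * 2 * 30), imaginary = rnorm(50 * 2 * 30)),
#'            dim = c(50, 2, 30))
#' s <- cfr_series(v, fs = 50)
#' s$n_subcarriers
cfr_series <- function(values, fs, t0 = 0) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-d array: packets x antennas x subcarriers")
  if (!is.complex(values)) {
    if (is.numeric(values)) {
      values <- array(as.complex(values), dim = dim(values))
    } else stop("`values` must be complex")
  }
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values))))
    stop("all CFR entries must be finite")
  if (!is_scalar_number(fs) || fs <= 0) stop("`fs` must be a positive number")
  d <- dim(values)
  if (d[1] < 1) stop("empty series: need at least one packet")
  if (d[2] < 1) stop("need at least one antenna")
  structure(
    list(values = values, fs = fs, t0 = t0,
         n_packets = d[1], n_antennas = d[2], n_subcarriers = d[3]),
    class = "cfr_series")
}

#' @export
print.cfr_series <- function(x, ...) {
  cat(sprintf(
    "<cfr_series> %d packets x %d antennas x %d subcarriers @ %g Hz (%.1f s)\n",
    x$n_packets, x$n_antennas, x$n_subcarriers, x$fs, x$n_packets / x$fs))
  invisible(x)
}

check_antenna <- function(series, antenna) {
  if (!is_scalar_number(antenna) || antenna != round(antenna))
    stop("`antenna` must be a single integer index (1-based)")
  if (antenna < 1 || antenna > series$n_antennas)
    stop(sprintf("antenna %d out of range (series has %d antennas)",
                 antenna, series$n_antennas))
  as.integer(antenna)
}

#' Subcarrier amplitude matrix
#'
#' Extracts the per-packet amplitude (complex modulus) of every subcarrier on
#' one receive antenna. The periodic chest excursion of breathing modulates
#' these amplitudes, so this matrix is the input to subcarrier selection and
#' all downstream processing.
#'
#' @param series a [cfr_series()].
#' @param antenna 1-based receive-antenna index.
#'
#' @return A numeric matrix of class `amplitude_matrix` (time x subcarrier,
#'   non-negative) with attributes `fs` (Hz) and `antenna`.
#' @export
amplitude <- function(series, antenna = 1) {
  stopifnot(inherits(series, "cfr_series"))
  antenna <- check_antenna(series, antenna)
  m <- Mod(series$values[, antenna, , drop = FALSE])
  m <- matrix(m, nrow = series$n_packets, ncol = series$n_subcarriers)
  structure(m, fs = series$fs, antenna = antenna,
            class = c("amplitude_matrix", "matrix"))
}

#' Subcarrier phase matrix
#'
#' Per-packet principal phase angle (radians, in `(-pi, pi]`) of every
#' subcarrier on one antenna. Raw CSI phase carries a random per-packet
#' offset and is not directly usable for sensing; it is retained for
#' completeness and as the input to [phase_difference()].
#'
#' @inheritParams amplitude
#' @return numeric matrix (time x subcarrier) of phase angles in radians.
#' @export
phase <- function(series, antenna = 1) {
  stopifnot(inherits(series, "cfr_series"))
  antenna <- check_antenna(series, antenna)
  matrix(Arg(series$values[, antenna, , drop = FALSE]),
         nrow = series$n_packets, ncol = series$n_subcarriers)
}

#' Phase difference between two receive antennas
#'
#' The random per-packet phase offset is common to all antennas, so the
#' difference of the phases observed at two antennas on the same subcarrier
#' cancels it, leaving a stable profile weakly modulated by body motion.
#' Phases are unwrapped along time on each antenna before differencing, and
#' the difference is re-wrapped to `(-pi, pi]`.
#'
#' @inheritParams amplitude
#' @param antenna_a,antenna_b distinct 1-based antenna indices.
#' @param subcarrier 1-based subcarrier index.
#' @return numeric vector of length `n_packets`, radians in `(-pi, pi]`.
#' @export
phase_difference <- function(series, antenna_a, antenna_b, subcarrier = 1) {
  stopifnot(inherits(series, "cfr_series"))
  antenna_a <- check_antenna(series, antenna_a)
  antenna_b <- check_antenna(series, antenna_b)
  if (antenna_a == antenna_b)
    stop("`antenna_a` and `antenna_b` must be distinct antennas")
  if (subcarrier < 1 || subcarrier > series$n_subcarriers)
    stop(sprintf("subcarrier %d out of range (series has %d subcarriers)",
                 subcarrier, series$n_subcarriers))
  pa <- signal::unwrap(Arg(series$values[, antenna_a, subcarrier]))
  pb <- signal::unwrap(Arg(series$values[, antenna_b, subcarrier]))
  wrap_pi(pa - pb)
}
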