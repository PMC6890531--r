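# Agreement between the wireless-derived waveform and the contact
# respiration sensor: range normalization, mean squared error and Pearson
# correlation on the normalized traces.

#' Normalize a series to a target range
#'
#' Affine map sending the series minimum to `a` and maximum to `b`:
#' `a + (x - min) / (max - min) * (b - a)`.
#'
#' @param x numeric series with `max(x) > min(x)`.
#' @param a,b target range endpoints (defaults -1 and 1).
#' @return numeric series with minimum exactly `a` and maximum exactly `b`.
#' @export
normalize_range <- function(x, a = -1, b = 1) {
  rng <- range(x)
  if (!(rng[2] > rng[1]))
    stop("cannot normalize a constant series")
  a + (x - rng[1]) / (rng[2] - rng[1]) * (b - a)
}

#' Mean squared error
#'
#' `mean((x_hat - x)^2)` between an estimated and a true series of equal
#' length.
#'
#' @param x_hat estimated series.
#' @param x reference series.
#' @return non-negative scalar.
#' @export
mse <- function(x_hat, x) {
  if (length(x_hat) != length(x))
    stop("`x_hat` and `x` must have the same length")
  mean((x_hat - x)^2)
}

#' Pearson correlation coefficient
#'
#' `cov(x, y) / (sd(x) sd(y))` with the population (1/n) convention; the
#' normalization cancels, so the value agrees with the sample convention.
#'
#' @param x,y numeric series of equal length (at least 2), both
#'   non-constant.
#' @return scalar in `[-1, 1]`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have the same length")
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sqrt(mean(xc^2))
  sy <- sqrt(mean(yc^2))
  if (sx == 0 || sy == 0)
    stop("Pearson correlation is undefined for a constant series")
  mean(xc * yc) / (sx * sy)
}

#' Agreement between wireless and sensor breathing traces
#'
#' Optionally aligns the two traces by the lag (within `± max_lag`
#' seconds) that maximizes their cross-correlation, normalizes both to
#' `[-1, 1]` over the overlapping region, and reports the mean squared
#' error and Pearson correlation of the normalized traces.
#'
#' @param wireless breathing waveform recovered from CSI (filtered
#'   subcarrier amplitude).
#' @param sensor contact-sensor reference trace at the same sampling rate.
#' @param fs sampling rate in Hz.
#' @param max_lag alignment search half-width in seconds (default 2); set
#'   `align = FALSE` for strict sample-by-sample comparison.
#' @param align logical; align by cross-correlation before comparing.
#' @return object of class `eval_report`: list with `mse`, `cc`,
#'   `lag_applied` (s; negative when the wireless trace lags the sensor),
#'   `n` (samples compared).
#' @export
evaluate_agreement <- function(wireless, sensor, fs, max_lag = 2,
                               align = TRUE) {
  stopifnot(is.numeric(wireless), is.numeric(sensor), fs > 0)
  lag <- 0L
  if (align) {
    lmax <- as.integer(round(max_lag * fs))
    lags <- seq.int(-lmax, lmax)
    w0 <- wireless - mean(wireless)
    s0 <- sensor - mean(sensor)
    score <- vapply(lags, function(l) {
      ov <- overlap_at_lag(length(w0), length(s0), l)
      if (ov$n < 2) return(-Inf)
      sum(w0[ov$wi] * s0[ov$si])
    }, numeric(1))
    lag <- lags[which.max(score)]
  }
  ov <- overlap_at_lag(length(wireless), length(sensor), lag)
  if (ov$n < 10 * fs)
    stop("overlap shorter than 10 s after alignment")
  w <- normalize_range(wireless[ov$wi])
  s <- normalize_range(sensor[ov$si])
  structure(list(mse = mse(w, s), cc = pearson_cc(w, s),
                 lag_applied = lag / fs, n = ov$n),
            class = "eval_report")
}

# Index sets of the overlap when the wireless trace is shifted by `lag`
# samples relative to the sensor (positive lag: wireless starts later).
overlap_at_lag <- function(nw, ns, lag) {
  wi0 <- max(1, 1 - lag)
  si0 <- max(1, 1 + lag)
  n <- min(nw - wi0, ns - si0) + 1
  list(wi = seq.int(wi0, length.out = max(n, 0)),
       si = seq.int(si0, length.out = max(n, 0)), n = max(n, 0))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> MSE %.4f, CC %.4f (lag %+.2f s, n = %d)\n",
              x$mse, x$cc, x$lag_applied, x$n))
  invisible(x)
}
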