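# Discrete wavelet transform (sym8) with symmetric signal extension, and
# soft heuristic-SURE threshold denoising.
#
# The decomposition uses the standard pyramid algorithm: extend the signal
# symmetrically by one filter length minus one on each side, convolve with
# the analysis filters, and keep every second coefficient; reconstruction
# upsamples, convolves with the synthesis filters and crops back to the
# original length (perfect reconstruction to machine precision).

# Symlet-8 analysis/synthesis filter banks (least-asymmetric Daubechies,
# 8 vanishing moments, 16 taps). Standard published constants.
SYM8_DEC_LO <- c(
  -3.38241595101377e-03, -5.42132331791774e-04,  3.16950878103452e-02,
   7.60748732491761e-03, -1.43294238350810e-01, -6.12733590676585e-02,
   4.81359651258372e-01,  7.77185751700524e-01,  3.64441894835331e-01,
  -5.19458381078751e-02, -2.72190299168137e-02,  4.91371796734768e-02,
   3.80875201389062e-03, -1.49522583367926e-02, -3.02920514721072e-04,
   1.88995033275946e-03)
SYM8_DEC_HI <- rev(SYM8_DEC_LO) * rep(c(-1, 1), 8)
SYM8_REC_LO <- rev(SYM8_DEC_LO)
SYM8_REC_HI <- rev(SYM8_DEC_HI)

# Symmetric (half-point, edge-repeating) extension by m samples per side;
# requires m <= length(x), which holds for every level when the input is at
# least one filter length long.
sym_extend <- function(x, m) {
  n <- length(x)
  stopifnot(m <= n)
  c(rev(x[seq_len(m)]), x, rev(x[seq.int(n - m + 1, n)]))
}

conv_full <- function(x, f) {
  # direct full convolution (filter lengths are small)
  n <- length(x); m <- length(f)
  y <- numeric(n + m - 1)
  for (j in seq_len(m)) y[j:(j + n - 1)] <- y[j:(j + n - 1)] + f[j] * x
  y
}

# One analysis step: returns approximation and detail coefficients of
# length floor((n + lf - 1) / 2).
dwt_step <- function(x, lo = SYM8_DEC_LO, hi = SYM8_DEC_HI) {
  lf <- length(lo)
  ext <- sym_extend(x, lf - 1)
  fa <- conv_full(ext, lo)
  fd <- conv_full(ext, hi)
  # drop the filter-transient edges, then keep every second coefficient
  keep <- seq.int(lf, length(fa) - lf + 1)
  idx <- keep[seq.int(2, length(keep), by = 2)]
  list(a = fa[idx], d = fd[idx])
}

# Inverse of dwt_step for an original length n.
idwt_step <- function(a, d, n, lo = SYM8_REC_LO, hi = SYM8_REC_HI) {
  lf <- length(lo)
  up <- function(c) {
    u <- numeric(2 * length(c))
    u[seq.int(2, length(u), by = 2)] <- c
    u
  }
  y <- conv_full(up(a), lo) + conv_full(up(d), hi)
  y[seq.int(lf, lf + n - 1)]
}

# Multilevel decomposition: list(a = deepest approximation,
# d = list of detail vectors, level 1 (finest) first, lengths = original
# lengths at each level).
wavedec_sym8 <- function(x, level) {
  stopifnot(level >= 1)
  d <- vector("list", level)
  lens <- integer(level)
  a <- x
  for (j in seq_len(level)) {
    lens[j] <- length(a)
    s <- dwt_step(a)
    d[[j]] <- s$d
    a <- s$a
  }
  list(a = a, d = d, lengths = lens)
}

waverec_sym8 <- function(dec) {
  a <- dec$a
  for (j in rev(seq_along(dec$d)))
    a <- idwt_step(a, dec$d[[j]], dec$lengths[j])
  a
}

# Fixed-form universal threshold sqrt(2 log n).
universal_threshold <- function(n) sqrt(2 * log(n))

# SURE-minimizing soft threshold for a unit-noise coefficient vector.
sure_threshold <- function(x) {
  n <- length(x)
  sx2 <- sort(x^2)
  risks <- (n - 2 * seq_len(n) + cumsum(sx2) +
              (n - seq_len(n)) * sx2) / n
  sqrt(sx2[which.min(risks)])
}

# Heuristic SURE: universal threshold when the coefficients are too sparse
# for a reliable risk estimate, otherwise min(SURE, universal).
heursure_threshold <- function(x) {
  n <- length(x)
  if (n == 0) return(0)
  magic <- universal_threshold(n)
  eta <- (sum(x^2) - n) / n
  crit <- (log2(n))^1.5 / sqrt(n)
  if (!is.finite(eta) || eta < crit) magic
  else min(sure_threshold(x), magic)
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

#' Filtering configuration
#'
#' Parameters of the two-stage denoiser: a sym8 wavelet filter with soft
#' heuristic-SURE thresholding of the detail coefficients (noise scale
#' estimated from the finest detail level and applied to all levels),
#' followed by a centered moving-average smoother.
#'
#' @param wavelet wavelet name; only `"sym8"` is implemented.
#' @param level decomposition depth (default 4).
#' @param ma_window moving-average window in seconds (default 1; removes
#'   noise above ~1 Hz without attenuating breaths, which are slower than
#'   1 Hz).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(wavelet = "sym8", level = 4, ma_window = 1.0) {
  if (!identical(wavelet, "sym8"))
    stop("only the sym8 wavelet is implemented")
  stopifnot(level >= 1, ma_window > 0)
  structure(list(wavelet = wavelet, level = as.integer(level),
                 threshold_rule = "heuristic_sure_soft",
                 noise_rescaling = "first_level_scaled",
                 ma_window = ma_window),
            class = "filter_config")
}

#' Wavelet denoising (sym8, soft heuristic-SURE thresholding)
#'
#' Decomposes the series to `cfg$level` levels with the sym8 wavelet,
#' soft-thresholds every detail level with a heuristic-SURE threshold, and
#' reconstructs. The noise scale is estimated once from the finest detail
#' level as `median(|d1|) / 0.6745` and applied to all levels. Removes
#' impulsive outliers and wideband noise while retaining sharp transitions.
#'
#' @param x numeric series, length at least `2^level`.
#' @param cfg a [filter_config()].
#' @return denoised numeric series of the same length.
#' @export
#' @examples
#' t <- (0:599) / 50
#' noisy <- sin(2 * pi * 0.25 * t) + rnorm(600, sd = 0.2)
#' clean <- wavelet_denoise(noisy)
wavelet_denoise <- function(x, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  n <- length(x)
  if (n < 2^cfg$level)
    stop(sprintf("series too short for a level-%d decomposition (need >= %d)",
                 cfg$level, 2^cfg$level))
  dec <- wavedec_sym8(x, cfg$level)
  sigma <- median(abs(dec$d[[1]])) / 0.6745
  if (sigma > 0) {
    for (j in seq_along(dec$d)) {
      thr <- sigma * heursure_threshold(dec$d[[j]] / sigma)
      dec$d[[j]] <- soft_threshold(dec$d[[j]], thr)
    }
  }
  waverec_sym8(dec)
}

#' Centered moving average
#'
#' Moving mean with a centered window that shrinks at the series edges, so
#' the output has the same length and full duration as the input. For even
#' windows the center is taken half a sample to the left.
#'
#' @param x numeric series.
#' @param window window length in samples (`1 <= window <= length(x)`).
#' @return smoothed numeric series, same length as `x`.
#' @export
moving_average <- function(x, window) {
  n <- length(x)
  if (!is_scalar_number(window) || window < 1)
    stop("`window` must be a positive number of samples")
  window <- as.integer(round(window))
  if (window > n) stop("`window` longer than the series")
  if (window == 1) return(x)
  h1 <- (window - 1) %/% 2
  h2 <- window - 1 - h1
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h1, 1)
  hi <- pmin(i + h2, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Two-stage denoising of a subcarrier amplitude series
#'
#' Applies [wavelet_denoise()] then [moving_average()] with the settings in
#' `cfg` — the standard cleaning step between subcarrier selection and rate
#' extraction.
#'
#' @param x numeric amplitude series.
#' @param fs sampling rate in Hz.
#' @param cfg a [filter_config()].
#' @return filtered numeric series, same length.
#' @export
filter_signal <- function(x, fs, cfg = filter_config()) {
  w <- max(1L, as.integer(round(cfg$ma_window * fs)))
  moving_average(wavelet_denoise(x, cfg), min(w, length(x)))
}
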