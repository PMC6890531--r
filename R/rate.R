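# Respiratory rate extraction: STFT spectrogram, dominant in-band
# frequency, peak-detection breath counting, and event read-outs
# (apnea intervals, sighs).

#' STFT magnitude spectrogram
#'
#' Divides the series into overlapping segments, applies a Hamming taper and
#' computes a zero-padded FFT of each. The defaults (512-sample window,
#' 511-sample overlap, 3000-point FFT at 50 Hz) give a time resolution of
#' 20 ms (the 1-sample hop) and a frequency resolution of 0.017 Hz —
#' fine enough to resolve breathing rates below 1 Hz.
#'
#' Each segment is demeaned (constant detrend) before tapering, so neither
#' the large constant amplitude offset of a CSI subcarrier nor slow
#' baseline shifts (e.g. the on/off gating of apneic breathing) leak into
#' the breathing band.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param window Hamming window length in samples (default 512).
#' @param overlap overlapping samples between consecutive segments
#'   (default 511; must be `< window`).
#' @param nfft FFT length, zero-padded (default 3000).
#' @param demean subtract each segment's mean before tapering
#'   (default TRUE).
#' @return object of class `spectrogram`: list with `magnitude`
#'   (freq x time matrix), `freqs` (Hz, `0 .. fs/2`), `times` (segment
#'   centers, s), `fs`, `window`, `overlap`, `nfft`, `hop`, `n_samples`.
#' @export
#' @examples
#' x <- sin(2 * pi * 0.25 * (0:2999) / 50)
#' sg <- stft_spectrogram(x, fs = 50)
#' ncol(sg$magnitude)  # 3000 - 512 + 1 = 2489 frames
stft_spectrogram <- function(x, fs, window = 512, overlap = 511,
                             nfft = 3000, demean = TRUE) {
  n <- length(x)
  if (n < window) stop("signal shorter than one analysis window")
  if (overlap >= window) stop("`overlap` must be smaller than `window`")
  if (nfft < window) stop("`nfft` must be at least the window length")
  hop <- window - overlap
  starts <- seq.int(1, n - window + 1, by = hop)
  nf <- nfft %/% 2 + 1
  taper <- as.numeric(signal::hamming(window))
  mag <- matrix(0, nrow = nf, ncol = length(starts))
  # frames processed in blocks to bound the size of the padded FFT matrix
  block <- max(1L, as.integer(2^22 / nfft))
  for (b0 in seq.int(1, length(starts), by = block)) {
    cols <- b0:min(b0 + block - 1, length(starts))
    seg <- vapply(starts[cols], function(s) {
      v <- x[s:(s + window - 1)]
      if (demean) v <- v - mean(v)
      v * taper
    }, numeric(window))
    padded <- rbind(seg, matrix(0, nfft - window, length(cols)))
    mag[, cols] <- abs(mvfft(padded))[seq_len(nf), , drop = FALSE]
  }
  structure(
    list(magnitude = mag,
         freqs = (seq_len(nf) - 1) * fs / nfft,
         times = (starts - 1 + (window - 1) / 2) / fs,
         fs = fs, window = window, overlap = overlap, nfft = nfft,
         hop = hop, n_samples = n),
    class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  r <- spectrogram_resolution(x)
  cat(sprintf(
    "<spectrogram> %d freqs x %d frames, window %d / overlap %d / nfft %d @ %g Hz\n",
    nrow(x$magnitude), ncol(x$magnitude), x$window, x$overlap, x$nfft, x$fs))
  cat(sprintf("  time resolution %g ms, frequency resolution %g Hz\n",
              r$time_ms, r$freq_hz))
  invisible(x)
}

#' Time and frequency resolution of a spectrogram
#'
#' Time resolution is the hop between consecutive frames (`hop / fs`);
#' frequency resolution is the FFT bin spacing (`fs / nfft`). Values are
#' reported as conventionally printed: milliseconds, and Hz rounded to
#' 3 decimals.
#'
#' @param sg a [stft_spectrogram()] object.
#' @return list with `time_s`, `time_ms`, `freq_hz` (rounded to 3 decimals)
#'   and `freq_hz_exact`.
#' @export
spectrogram_resolution <- function(sg) {
  stopifnot(inherits(sg, "spectrogram"))
  dt <- sg$hop / sg$fs
  df <- sg$fs / sg$nfft
  list(time_s = dt, time_ms = dt * 1000,
       freq_hz = round(df, 3), freq_hz_exact = df)
}

#' Respiratory rate estimate
#'
#' @param hz rate in Hz.
#' @param method `"stft"` or `"peak_count"`.
#' @param band frequency band searched, Hz (for STFT estimates).
#' @param count breath count (for peak-count estimates; may be
#'   half-integral when a trailing unpaired inhale counts 0.5).
#' @param duration record duration in seconds.
#' @return list of class `rate_estimate` with `hz`, `breaths_per_min`
#'   (`60 * hz`), `method`, `band`, `count`, `duration`.
#' @export
rate_estimate <- function(hz, method, band = NULL, count = NA,
                          duration = NA) {
  structure(list(hz = hz, breaths_per_min = 60 * hz, method = method,
                 band = band, count = count, duration = duration),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %.2f Hz (%.1f breaths/min) by %s\n",
              x$hz, x$breaths_per_min, x$method))
  invisible(x)
}

#' Convert a breath count to a rate
#'
#' `count / duration`, in Hz. A count of 18.5 breaths over 110 s gives
#' 0.17 Hz (2-decimal rounding); rates convert to breaths/min as `60 * hz`
#' (0.26 Hz is 15.6 breaths/min).
#'
#' @param count number of breaths (half-breaths allowed).
#' @param duration seconds.
#' @return `rate_estimate` with method `"peak_count"`.
#' @export
breaths_to_rate <- function(count, duration) {
  stopifnot(count >= 0, duration > 0)
  rate_estimate(count / duration, "peak_count", count = count,
                duration = duration)
}

#' Dominant in-band frequency of a spectrogram
#'
#' Averages the magnitude over time, restricts to the breathing band and
#' returns the frequency bin with the maximum mean magnitude. The estimate
#' is quantized to the spectrogram's frequency grid (`fs / nfft`).
#'
#' @param sg a [stft_spectrogram()] object.
#' @param band `c(low, high)` search band in Hz; the default
#'   `c(0.05, 1)` spans human breathing while excluding DC leakage.
#' @return `rate_estimate` with method `"stft"`.
#' @export
dominant_frequency <- function(sg, band = c(0.05, 1.0)) {
  stopifnot(inherits(sg, "spectrogram"), length(band) == 2,
            band[2] > band[1])
  sel <- which(sg$freqs >= band[1] & sg$freqs <= band[2])
  if (length(sel) == 0)
    stop("empty band: no frequency bins between band limits")
  avg <- rowMeans(sg$magnitude[sel, , drop = FALSE])
  if (max(avg) <= .Machine$double.eps * 100)
    stop("no in-band peak: spectrogram has no energy in the breathing band")
  rate_estimate(sg$freqs[sel[which.max(avg)]], "stft", band = band)
}

# Local maxima with prominence. Returns a data.frame(index, height,
# prominence), unfiltered.
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(data.frame(index = integer(0), height = numeric(0),
                               prominence = numeric(0)))
  d <- diff(x)
  # rising then falling (plateaus count once, at their left edge)
  rise <- c(FALSE, d > 0)
  fall <- c(d < 0, FALSE)
  flat <- c(FALSE, d == 0)
  # propagate a rise across plateaus
  state <- rise
  for (i in which(flat)) state[i] <- state[i - 1]
  idx <- which(state & fall)
  if (length(idx) == 0)
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(idx, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    hi_l <- which(left > h)
    lmin <- if (length(hi_l)) min(left[(max(hi_l) + 1):(p - 1)]) else min(left)
    right <- x[seq.int(p + 1, n)]
    hi_r <- which(right > h)
    rmin <- if (length(hi_r)) min(right[seq_len(min(hi_r) - 1)]) else min(right)
    h - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = idx, height = x[idx], prominence = prom)
}

# Peaks filtered by a prominence floor and a minimum spacing (greedy,
# keeping the more prominent peak).
breath_peaks <- function(x, fs, min_prominence, min_spacing_s = 1) {
  pk <- find_peaks(x)
  pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
  if (nrow(pk) <= 1) return(pk)
  pk <- pk[order(-pk$prominence), ]
  keep <- logical(nrow(pk))
  taken <- numeric(0)
  gap <- min_spacing_s * fs
  for (i in seq_len(nrow(pk))) {
    if (all(abs(pk$index[i] - taken) >= gap)) {
      keep[i] <- TRUE
      taken <- c(taken, pk$index[i])
    }
  }
  pk <- pk[keep, , drop = FALSE]
  pk[order(pk$index), , drop = FALSE]
}

#' Count breaths by peak detection
#'
#' Detects inhale peaks as local maxima with prominence at least 0.3x the
#' inter-quartile range of the (filtered) signal and at least 1 s apart
#' (breathing is slower than 1 Hz). A trailing rising half-cycle — a final
#' inhale without a completing exhale — counts as half a breath, matching
#' the convention of quoting e.g. "18.5 breaths".
#'
#' @param x filtered breathing signal.
#' @param fs sampling rate in Hz.
#' @return list with `count` (possibly half-integral), `rate` (a
#'   `rate_estimate`; `hz = count / duration`), `peak_times` (s) and
#'   `peak_indices`. For a flat signal, `count` is 0 and `rate$hz` is `NA`
#'   (undefined).
#' @export
count_breaths <- function(x, fs) {
  n <- length(x)
  duration <- n / fs
  if (duration < 10)
    stop("record shorter than one maximal breath period (10 s)")
  iqr <- diff(quantile(x, c(0.25, 0.75), names = FALSE))
  if (iqr <= .Machine$double.eps * 100) {
    est <- rate_estimate(NA_real_, "peak_count", count = 0,
                         duration = duration)
    return(list(count = 0, rate = est, peak_times = numeric(0),
                peak_indices = integer(0)))
  }
  pk <- breath_peaks(x, fs, min_prominence = 0.3 * iqr)
  count <- nrow(pk)
  # trailing unpaired inhale: after the last peak the signal rises by at
  # least half a typical breath and does not fall back by half that rise
  if (count >= 1) {
    tail_seg <- x[pk$index[count]:n]
    tmin <- which.min(tail_seg)
    post <- tail_seg[tmin:length(tail_seg)]
    rise <- max(post) - post[1]
    fall_back <- max(post) - post[length(post)]
    if (rise >= 0.5 * median(pk$prominence) && fall_back < 0.5 * rise)
      count <- count + 0.5
  }
  list(count = count,
       rate = breaths_to_rate(count, duration),
       peak_times = (pk$index - 1) / fs,
       peak_indices = pk$index)
}

#' Detect apnea intervals from a spectrogram
#'
#' Flags spectrogram frames whose in-band power (summed squared magnitude
#' over the breathing band) falls below `threshold` times the median
#' in-band power, then refines the boundaries of each flagged run to the
#' point of steepest power change within half an analysis window of the
#' run edge. The long analysis window smears the power step at an apnea
#' boundary over its full width, so a fixed-fraction crossing is biased
#' inward; for a step blurred by a symmetric window the maximum-gradient
#' point recovers the true boundary (classic step-edge localization).
#' Refined runs are merged, intervals shorter than `min_duration` are
#' dropped, and runs reaching the first or last frame are extended to the
#' record edges. If the record carries no in-band power at all, the whole
#' record is returned as a single apnea.
#'
#' @param sg a [stft_spectrogram()] object.
#' @param band breathing band in Hz (default `c(0.05, 1)`).
#' @param min_duration minimum apnea length in seconds (default 5).
#' @param threshold core flagging fraction of the median in-band power
#'   (default 0.2).
#' @return data.frame with columns `start`, `end` (seconds), possibly with
#'   zero rows.
#' @export
detect_apneas <- function(sg, band = c(0.05, 1.0), min_duration = 5,
                          threshold = 0.2) {
  stopifnot(inherits(sg, "spectrogram"))
  sel <- which(sg$freqs >= band[1] & sg$freqs <= band[2])
  if (length(sel) == 0) stop("empty band")
  p <- colSums(sg$magnitude[sel, , drop = FALSE]^2)
  m <- ncol(sg$magnitude)
  duration <- sg$n_samples / sg$fs
  med <- median(p)
  if (med <= .Machine$double.eps * 100) {
    return(data.frame(start = 0, end = duration))
  }
  frame_dt <- sg$hop / sg$fs
  # smoothed power and a +/-0.5 s central-difference gradient
  ps <- moving_average(p, max(1L, as.integer(round(1 / frame_dt))))
  half <- max(1L, as.integer(round(0.5 / frame_dt)))
  grad <- c(rep(NA_real_, half),
            ps[(2 * half + 1):m] - ps[1:(m - 2 * half)],
            rep(NA_real_, half))
  search <- as.integer(round(sg$window / (2 * sg$hop)))  # half window

  core <- p < threshold * med
  r <- rle(core)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (length(runs) == 0)
    return(data.frame(start = numeric(0), end = numeric(0)))
  iv <- lapply(runs, function(i) {
    a <- starts[i]; b <- ends[i]
    # steepest decline before the run start, steepest incline after its end
    la <- max(1, a - search)
    ga <- grad[la:a]
    if (any(is.finite(ga))) a <- la + which.min(ga) - 1
    rb <- min(m, b + search)
    gb <- grad[b:rb]
    if (any(is.finite(gb))) b <- b + which.max(gb) - 1
    t0 <- if (starts[i] == 1) 0 else sg$times[a]
    t1 <- if (ends[i] == m) duration else sg$times[b]
    c(t0, t1)
  })
  iv <- do.call(rbind, iv)
  out <- data.frame(start = iv[, 1], end = iv[, 2])
  # merge overlapping refined intervals
  if (nrow(out) > 1) {
    keep <- list(unlist(out[1, ]))
    for (i in 2:nrow(out)) {
      last <- keep[[length(keep)]]
      if (out$start[i] <= last[2])
        keep[[length(keep)]] <- c(last[1], max(last[2], out$end[i]))
      else keep[[length(keep) + 1]] <- unlist(out[i, ])
    }
    iv <- do.call(rbind, keep)
    out <- data.frame(start = iv[, 1], end = iv[, 2])
  }
  out <- out[out$end - out$start >= min_duration, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect sighs by peak amplitude
#'
#' Finds breath peaks as in [count_breaths()] and flags those whose
#' prominence is at least `ratio` times the median breath prominence.
#' The default ratio 1.4 sits just below the physiological sigh range
#' (1.5-2x tidal volume) to allow for attenuation by filtering.
#'
#' @param x filtered breathing signal containing at least 5 breaths.
#' @param fs sampling rate in Hz.
#' @param ratio sigh threshold relative to the median breath (default 1.4).
#' @return numeric vector of sigh times in seconds (possibly empty).
#' @export
detect_sighs <- function(x, fs, ratio = 1.4) {
  iqr <- diff(quantile(x, c(0.25, 0.75), names = FALSE))
  if (iqr <= .Machine$double.eps * 100)
    stop("too few breaths to establish a median breath amplitude")
  pk <- breath_peaks(x, fs, min_prominence = 0.3 * iqr)
  if (nrow(pk) < 5)
    stop("too few breaths to establish a median breath amplitude")
  med <- median(pk$prominence)
  (pk$index[pk$prominence >= ratio * med] - 1) / fs
}
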