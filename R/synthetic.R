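#' Breathing pattern waveform generator
#'
#' Generates a ground-truth chest-displacement series for one of six
#' breathing patterns: `normal` (steady quasi-sinusoidal breaths),
#' `biots` (regular deep breaths interspersed with apnea periods),
#' `cheyne_stokes` (crescendo-decrescendo breathing alternating with apnea),
#' `ataxic` (unpredictably irregular rate, depth and pauses),
#' `kussmaul` (deep breathing, here at its characteristic fast rate) and
#' `sighing` (normal breathing punctuated by sighs 1.5-2x the usual tidal
#' volume).
#'
#' Each breath is a raised-cosine pulse of one breath period, so inhale peaks
#' are well defined for peak counting; contiguous equal breaths tile into an
#' exact sinusoid plus offset. A slow low-amplitude baseline drift (3% of
#' depth) emulates residual body sway, so apneas are near-flat rather than
#' exactly zero.
#'
#' @param pattern one of `"normal"`, `"biots"`, `"cheyne_stokes"`,
#'   `"ataxic"`, `"kussmaul"`, `"sighing"`.
#' @param duration record length in seconds.
#' @param fs sampling rate in Hz (default 50).
#' @param rate_bpm nominal breathing rate in breaths/min. Defaults: 15 for
#'   most patterns; 21.6 (0.36 Hz) for `kussmaul`.
#' @param depth nominal breath depth (peak chest excursion, arbitrary
#'   units). Default 1; `biots` and `kussmaul` default to deep breaths
#'   (2x).
#' @param apnea_intervals list of `c(start, end)` second pairs (used by
#'   `biots`; defaults to three pauses at 20-30 s, 55-65 s and 95-105 s).
#' @param sigh_times seconds at which sighs are scheduled (used by
#'   `sighing`; default `c(10, 22, 35, 47, 58)`, trimmed to `duration`).
#' @param sigh_ratio sigh amplitude relative to a usual breath; values
#'   outside `[1.5, 2]` trigger a warning.
#' @param cs_cycle,cs_apnea Cheyne-Stokes cycle: `cs_cycle` seconds of
#'   crescendo-decrescendo breathing followed by `cs_apnea` seconds of
#'   apnea (defaults 40 and 10).
#' @param seed integer seed controlling every random element (ataxic
#'   segments, drift phase).
#'
#' @return Object of class `breathing_waveform`: list with `displacement`
#'   (numeric, length `duration * fs`), `fs`, `pattern`, `nominal_rate_hz`,
#'   `apnea_intervals` (list of second pairs), `sigh_times`,
#'   `breath_onsets` (seconds), `duration`.
#' @export
#' @examples
#' w <- generate_waveform("normal", duration = 60, fs = 50, rate_bpm = 15)
#' length(w$displacement)  # 3000
generate_waveform <- function(pattern = c("normal", "biots", "cheyne_stokes",
                                          "ataxic", "kussmaul", "sighing"),
                              duration, fs = 50,
                              rate_bpm = NULL, depth = NULL,
                              apnea_intervals = NULL,
                              sigh_times = NULL, sigh_ratio = 1.8,
                              cs_cycle = 40, cs_apnea = 10,
                              seed = 1) {
  pattern <- match.arg(pattern)
  if (!is_scalar_number(duration) || duration <= 0)
    stop("`duration` must be a positive number of seconds")
  if (!is_scalar_number(fs) || fs <= 0) stop("`fs` must be positive")

  rate_bpm <- rate_bpm %||% switch(pattern, kussmaul = 21.6, 15)
  depth <- depth %||% switch(pattern, biots = 2, kussmaul = 2, 1)
  period <- 60 / rate_bpm

  breaths <- NULL     # data.frame(onset, period, depth)
  apneas <- list()
  sighs <- numeric(0)

  with_local_seed(seed, {
    if (pattern %in% c("normal", "kussmaul")) {
      breaths <- fill_breaths(0, duration, period, depth)
    } else if (pattern == "biots") {
      apneas <- apnea_intervals %||%
        list(c(20, 30), c(55, 65), c(95, 105))
      apneas <- validate_apneas(apneas, duration)
      breaths <- fill_breaths_around(duration, period, depth, apneas)
    } else if (pattern == "cheyne_stokes") {
      t <- 0
      breaths <- list()
      while (t < duration) {
        seg_end <- min(t + cs_cycle, duration)
        b <- fill_breaths(t, seg_end, period, depth)
        if (nrow(b) > 0) {
          # piecewise-linear crescendo-decrescendo envelope over the segment
          mid <- t + (seg_end - t) / 2
          peak_t <- b$onset + b$period / 2
          env <- 1 - abs(peak_t - mid) / ((seg_end - t) / 2)
          b$depth <- depth * (0.15 + 0.85 * pmax(env, 0))
          breaths[[length(breaths) + 1]] <- b
        }
        if (t + cs_cycle < duration) {
          ap_end <- min(t + cs_cycle + cs_apnea, duration)
          apneas[[length(apneas) + 1]] <- c(t + cs_cycle, ap_end)
        }
        t <- t + cs_cycle + cs_apnea
      }
      breaths <- do.call(rbind, breaths)
    } else if (pattern == "ataxic") {
      t <- 0
      breaths <- list()
      while (t < duration) {
        seg_len <- runif(1, 5, 10)
        seg_end <- min(t + seg_len, duration)
        if (runif(1) < 0.2) {
          if (seg_end - t >= 2) apneas[[length(apneas) + 1]] <- c(t, seg_end)
        } else {
          seg_rate <- runif(1, 0.1, 0.5)              # Hz
          seg_depth <- depth * runif(1, 0.3, 1.5)
          b <- fill_breaths(t, seg_end, 1 / seg_rate, seg_depth)
          if (nrow(b) > 0) breaths[[length(breaths) + 1]] <- b
        }
        t <- seg_end
      }
      breaths <- do.call(rbind, breaths)
    } else if (pattern == "sighing") {
      if (sigh_ratio < 1.5 || sigh_ratio > 2)
        warning("`sigh_ratio` outside the physiological range [1.5, 2]")
      sighs <- sigh_times %||% c(10, 22, 35, 47, 58)
      sighs <- sort(sighs[sighs < duration])
      breaths <- fill_breaths(0, duration, period, depth)
      if (nrow(breaths) > 0) {
        peak_t <- breaths$onset + breaths$period / 2
        for (s in sighs) {
          i <- which.min(abs(peak_t - s))
          breaths$depth[i] <- depth * sigh_ratio
        }
      }
    }

    if (is.null(breaths) || nrow(breaths) == 0)
      stop("pattern parameters produced no breaths")

    n <- round(duration * fs)
    disp <- render_breaths(breaths, n, fs)
    # slow baseline drift (<= 5% of depth) so apneas are near-flat, not zero
    tt <- (seq_len(n) - 1) / fs
    disp <- disp + 0.03 * depth * sin(2 * pi * tt / 60 + runif(1, 0, 2 * pi))

    structure(
      list(displacement = disp, fs = fs, pattern = pattern,
           nominal_rate_hz = rate_bpm / 60,
           depth = depth,
           apnea_intervals = apneas,
           sigh_times = sighs,
           breath_onsets = breaths$onset,
           duration = duration),
      class = "breathing_waveform")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_apneas <- function(apneas, duration) {
  apneas <- lapply(apneas, function(iv) {
    if (length(iv) != 2 || iv[2] <= iv[1])
      stop("each apnea interval must be c(start, end) with end > start")
    iv
  })
  starts <- vapply(apneas, `[`, 0, 1)
  ends <- vapply(apneas, `[`, 0, 2)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; apneas <- apneas[o]
  if (any(ends > duration))
    stop("apnea schedule exceeds the record duration")
  if (length(apneas) > 1 && any(starts[-1] < ends[-length(ends)]))
    stop("apnea intervals must not overlap")
  apneas
}

# Complete breaths of fixed period/depth tiling [from, to).
fill_breaths <- function(from, to, period, depth) {
  k <- floor((to - from) / period + 1e-9)
  if (k <= 0) return(data.frame(onset = numeric(0), period = numeric(0),
                                depth = numeric(0)))
  data.frame(onset = from + (seq_len(k) - 1) * period,
             period = period, depth = depth)
}

# Fill breaths over [0, duration], leaving the given apnea intervals (and any
# partial-breath gap immediately before them) flat.
fill_breaths_around <- function(duration, period, depth, apneas) {
  out <- list()
  t <- 0
  repeat {
    if (t + period > duration + 1e-9) break
    hit <- FALSE
    for (iv in apneas) {
      if (t < iv[2] - 1e-9 && t + period > iv[1] + 1e-9) {
        t <- iv[2]
        hit <- TRUE
        break
      }
    }
    if (hit) next
    out[[length(out) + 1]] <- data.frame(onset = t, period = period,
                                         depth = depth)
    t <- t + period
  }
  do.call(rbind, out)
}

# Render raised-cosine breath pulses into a displacement vector of n samples.
render_breaths <- function(breaths, n, fs) {
  disp <- numeric(n)
  for (i in seq_len(nrow(breaths))) {
    i0 <- round(breaths$onset[i] * fs) + 1
    len <- max(round(breaths$period[i] * fs), 2)
    idx <- i0:min(i0 + len - 1, n)
    ph <- (seq_along(idx) - 1) / len
    disp[idx] <- disp[idx] +
      breaths$depth[i] * 0.5 * (1 - cos(2 * pi * ph))
  }
  disp
}

#' @export
print.breathing_waveform <- function(x, ...) {
  cat(sprintf("<breathing_waveform> %s, %.0f s @ %g Hz, nominal %.2f Hz",
              x$pattern, x$duration, x$fs, x$nominal_rate_hz))
  if (length(x$apnea_intervals))
    cat(sprintf(", %d apneas", length(x$apnea_intervals)))
  if (length(x$sigh_times))
    cat(sprintf(", %d sighs", length(x$sigh_times)))
  cat("\n")
  invisible(x)
}

#' Simulated radio channel parameters
#'
#' Parameters of the synthetic CSI channel: each subcarrier's amplitude is an
#' affine function of chest displacement (`baseline + sensitivity x
#' displacement`) plus Gaussian noise, and a small set of designated
#' subcarriers additionally carries sparse multiplicative outlier bursts,
#' emulating the heterogeneous sensitivity and chaotic outlier-laden
#' subcarriers seen in real CSI amplitude records.
#'
#' One "planted" subcarrier is strongly breathing-sensitive (gain at least
#' 3x the median gain); it is the target that subcarrier selection should
#' recover.
#'
#' @param n_subcarriers number of OFDM subcarriers (default 30).
#' @param planted 1-based index of the strongly breathing-coupled
#'   subcarrier (default 14).
#' @param baseline per-subcarrier constant amplitude; default drawn
#'   uniformly in `[10, 20]` (seeded).
#' @param sensitivity per-subcarrier displacement-to-amplitude gain; default
#'   1 for the planted subcarrier and uniform `[0.05, 0.25]` elsewhere.
#' @param noise_sd additive Gaussian amplitude noise (default 0.15).
#' @param outlier_subcarriers subcarriers carrying outlier bursts (default
#'   `c(5, 21)`).
#' @param outlier_rate expected bursts per second on each designated
#'   subcarrier (default 0.5).
#' @param outlier_scale multiplicative burst amplitude factor (default 3).
#' @param phase_mod peak phase modulation by breathing, radians
#'   (default 0.2).
#' @param sensor_noise_sd additive noise of the simulated contact reference
#'   sensor (default 0.03, displacement units).
#' @param seed integer seed for channel draws and noise.
#' @return list of class `channel_params`.
#' @export
channel_params <- function(n_subcarriers = 30, planted = 14,
                           baseline = NULL, sensitivity = NULL,
                           noise_sd = 0.15,
                           outlier_subcarriers = c(5, 21),
                           outlier_rate = 0.5, outlier_scale = 3,
                           phase_mod = 0.2, sensor_noise_sd = 0.03,
                           seed = 1) {
  stopifnot(n_subcarriers >= 2, planted >= 1, planted <= n_subcarriers,
            noise_sd >= 0, outlier_rate >= 0, outlier_scale >= 1)
  with_local_seed(seed + 90001L, {
    if (is.null(baseline)) baseline <- runif(n_subcarriers, 10, 20)
    if (is.null(sensitivity)) {
      sensitivity <- runif(n_subcarriers, 0.05, 0.25)
      sensitivity[planted] <- 1
    }
  })
  stopifnot(length(baseline) == n_subcarriers,
            length(sensitivity) == n_subcarriers)
  if (max(sensitivity) < 3 * median(sensitivity))
    stop("no planted breathing-sensitive subcarrier: max sensitivity ",
         "must be >= 3x the median")
  structure(
    list(n_subcarriers = n_subcarriers, planted = planted,
         baseline = baseline, sensitivity = sensitivity,
         noise_sd = noise_sd,
         outlier_subcarriers = outlier_subcarriers,
         outlier_rate = outlier_rate, outlier_scale = outlier_scale,
         phase_mod = phase_mod, sensor_noise_sd = sensor_noise_sd,
         seed = seed),
    class = "channel_params")
}

#' Simulate a CSI record modulated by a breathing waveform
#'
#' Produces a complex CFR packet stream whose subcarrier amplitudes follow
#' `baseline + sensitivity x displacement` plus noise and outlier bursts
#' (see [channel_params()]), together with a simulated contact-sensor
#' reference trace (displacement plus independent sensor noise) at the same
#' sampling rate. Packet phases carry a random common offset per packet plus
#' a stable per-antenna offset weakly modulated by the displacement, so the
#' antenna-pair phase difference is stable while the raw phase is random.
#'
#' @param waveform a [generate_waveform()] result.
#' @param channel a [channel_params()] object.
#' @param antennas number of receive antennas (default 3).
#' @return list with `csi` (a [cfr_series()]) and `reference` (numeric).
#' @export
simulate_csi <- function(waveform, channel = channel_params(),
                         antennas = 3) {
  stopifnot(inherits(waveform, "breathing_waveform"),
            inherits(channel, "channel_params"), antennas >= 1)
  disp <- waveform$displacement
  n <- length(disp)
  K <- channel$n_subcarriers
  fs <- waveform$fs

  with_local_seed(channel$seed + 77003L, {
    amps <- array(0, dim = c(n, antennas, K))
    for (a in seq_len(antennas)) {
      base <- matrix(rep(channel$baseline, each = n), n, K) +
        outer(disp, channel$sensitivity)
      if (channel$noise_sd > 0)
        base <- base + matrix(rnorm(n * K, sd = channel$noise_sd), n, K)
      for (k in channel$outlier_subcarriers) {
        if (k < 1 || k > K) next
        nb <- rpois(1, channel$outlier_rate * n / fs)
        if (nb > 0) {
          at <- sample.int(n, min(nb, n))
          base[at, k] <- base[at, k] * channel$outlier_scale
        }
      }
      amps[, a, ] <- pmax(base, 1e-3)
    }
    dmax <- max(abs(disp), 1e-12)
    theta_common <- runif(n, -pi, pi)
    ant_offset <- runif(antennas, -pi, pi)
    ant_mod <- runif(antennas, 0, 1)
    ph <- array(0, dim = c(n, antennas, K))
    for (a in seq_len(antennas))
      ph[, a, ] <- theta_common + ant_offset[a] +
        channel$phase_mod * ant_mod[a] * disp / dmax
    values <- amps * exp(1i * ph)
    reference <- disp +
      if (channel$sensor_noise_sd > 0)
        rnorm(n, sd = channel$sensor_noise_sd) else 0
    list(csi = cfr_series(values, fs = fs), reference = reference)
  })
}
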