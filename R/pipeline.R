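# End-to-end pipeline: subcarrier selection -> filtering -> rate/event
# extraction -> agreement with the reference sensor.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the sensing pipeline. The defaults
#' reproduce the reference prototype settings: 50 Hz sampling, Hamming
#' window of 512 samples with 511-sample overlap and a 3000-point FFT,
#' breathing band 0.05-1 Hz, sym8 level-4 wavelet denoising with a 1-s
#' moving average.
#'
#' @param antenna 1-based receive antenna to analyze (default 1).
#' @param subcarrier optional pinned subcarrier (1-based); `NULL` (default)
#'   lets the scoring mechanism choose.
#' @param filter a [filter_config()].
#' @param stft_window,stft_overlap,stft_nfft STFT parameters in samples.
#' @param band breathing band `c(low, high)` in Hz.
#' @param envelope_window envelope window for subcarrier scoring, seconds.
#' @param max_lag,align agreement-alignment settings, see
#'   [evaluate_agreement()].
#' @param apnea_min_duration,apnea_threshold apnea detector settings, see
#'   [detect_apneas()].
#' @param sigh_ratio sigh threshold, see [detect_sighs()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(antenna = 1, subcarrier = NULL,
                            filter = filter_config(),
                            stft_window = 512, stft_overlap = 511,
                            stft_nfft = 3000,
                            band = c(0.05, 1.0),
                            envelope_window = 2,
                            max_lag = 2, align = TRUE,
                            apnea_min_duration = 5, apnea_threshold = 0.2,
                            sigh_ratio = 1.4) {
  structure(
    list(antenna = antenna, subcarrier = subcarrier, filter = filter,
         stft_window = stft_window, stft_overlap = stft_overlap,
         stft_nfft = stft_nfft, band = band,
         envelope_window = envelope_window,
         max_lag = max_lag, align = align,
         apnea_min_duration = apnea_min_duration,
         apnea_threshold = apnea_threshold, sigh_ratio = sigh_ratio),
    class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full breathing-sensing pipeline
#'
#' Executes subcarrier selection, two-stage filtering, STFT and
#' peak-counting rate extraction, apnea and sigh detection and (when a
#' reference trace is supplied) agreement evaluation. Stage failures are
#' reported with the stage name; the sigh and breath-count detectors
#' degrade to `NULL` with a recorded note when the record does not support
#' them (e.g. too few breaths).
#'
#' @param csi a [cfr_series()].
#' @param sensor optional numeric reference trace at the same sampling
#'   rate.
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `subcarrier`
#'   (selected index), `scores` (score table), `filtered` (cleaned
#'   amplitude series), `rate_stft`, `rate_peaks`, `breath_count`,
#'   `apneas`, `sighs`, `evaluation` (or `NULL`), `notes` (character),
#'   `config` and `fs`.
#' @export
#' @examples
#' w <- generate_waveform("normal", duration = 60, fs = 50)
#' sim <- simulate_csi(w, channel_params(seed = 7), antennas = 3)
#' res <- run_pipeline(sim$csi, sim$reference)
#' res$rate_stft$hz
run_pipeline <- function(csi, sensor = NULL, config = pipeline_config()) {
  stopifnot(inherits(csi, "cfr_series"),
            inherits(config, "pipeline_config"))
  fs <- csi$fs
  notes <- character(0)

  amps <- run_stage("select", amplitude(csi, config$antenna))
  sel <- run_stage("select", select_subcarrier(
    amps, fs = fs, window = config$envelope_window))
  sc <- config$subcarrier %||% sel$index

  filtered <- run_stage("filter",
                        filter_signal(amps[, sc], fs, config$filter))

  sg <- run_stage("analyze", stft_spectrogram(
    filtered, fs, window = config$stft_window,
    overlap = config$stft_overlap, nfft = config$stft_nfft))
  rate_stft <- run_stage("analyze", dominant_frequency(sg, config$band))
  bc <- tryCatch(count_breaths(filtered, fs), error = function(e) {
    notes <<- c(notes, paste0("peak counting unavailable: ",
                              conditionMessage(e)))
    NULL
  })
  apneas <- run_stage("analyze", detect_apneas(
    sg, band = config$band, min_duration = config$apnea_min_duration,
    threshold = config$apnea_threshold))
  sighs <- tryCatch(detect_sighs(filtered, fs, ratio = config$sigh_ratio),
                    error = function(e) {
    notes <<- c(notes, paste0("sigh detection unavailable: ",
                              conditionMessage(e)))
    NULL
  })

  evaluation <- NULL
  if (!is.null(sensor)) {
    evaluation <- run_stage("evaluate", evaluate_agreement(
      filtered, sensor, fs, max_lag = config$max_lag,
      align = config$align))
  }

  structure(
    list(subcarrier = sc, scores = sel$table, filtered = filtered,
         rate_stft = rate_stft,
         rate_peaks = if (!is.null(bc)) bc$rate else NULL,
         breath_count = if (!is.null(bc)) bc$count else NULL,
         breath_peak_times = if (!is.null(bc)) bc$peak_times else NULL,
         apneas = apneas, sighs = sighs, evaluation = evaluation,
         notes = notes, config = config, fs = fs),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  selected subcarrier: %d\n", x$subcarrier))
  cat(sprintf("  STFT rate: %.2f Hz (%.1f breaths/min)\n",
              x$rate_stft$hz, x$rate_stft$breaths_per_min))
  if (!is.null(x$rate_peaks) && is.finite(x$rate_peaks$hz))
    cat(sprintf("  peak-count rate: %.2f Hz (%g breaths / %.0f s)\n",
                x$rate_peaks$hz, x$breath_count,
                x$rate_peaks$duration))
  cat(sprintf("  apneas: %d, sighs: %d\n",
              nrow(x$apneas), length(x$sighs %||% numeric(0))))
  if (!is.null(x$evaluation))
    cat(sprintf("  agreement: MSE %.4f, CC %.4f\n",
                x$evaluation$mse, x$evaluation$cc))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Serialize a pipeline result to JSON
#'
#' Writes rates, events, agreement statistics and the fully resolved
#' configuration (audit trail) as JSON. Identical input and configuration
#' produce byte-identical reports.
#'
#' @param result a [run_pipeline()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  rep <- list(
    subcarrier = result$subcarrier,
    rate = list(
      stft_hz = result$rate_stft$hz,
      stft_breaths_per_min = round(result$rate_stft$breaths_per_min, 1),
      peak_count = result$breath_count,
      peak_hz = if (!is.null(result$rate_peaks))
        round(result$rate_peaks$hz, 2) else NULL),
    events = list(
      apneas = result$apneas,
      sighs = result$sighs %||% numeric(0),
      breath_peak_times = result$breath_peak_times %||% numeric(0)),
    evaluation = if (!is.null(result$evaluation))
      result$evaluation[c("mse", "cc", "lag_applied", "n")] else NULL,
    notes = result$notes,
    config = unclass_deep(result$config),
    fs = result$fs)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = 10,
                       null = "null", dataframe = "columns")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
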