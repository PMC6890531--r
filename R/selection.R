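# Scoring-based subcarrier selection.
#
# Subcarriers differ in their sensitivity to breathing; some carry mostly
# noise, and a few carry chaotic outlier bursts that inflate their variance
# without carrying a usable waveform. Selection scores every subcarrier on
# (i) amplitude variance (higher = more breathing-coupled) and (ii) the mean
# gap between the upper envelope and the signal (an outlier index), and picks
# the best rank-sum.

#' Per-subcarrier amplitude variance
#'
#' Population variance (divisor `n`) of each subcarrier's amplitude series.
#'
#' @param amps an [amplitude()] matrix (time x subcarrier), or any numeric
#'   matrix with time in rows.
#' @return numeric vector, one variance per subcarrier.
#' @export
variance_scores <- function(amps) {
  amps <- as.matrix(amps)
  if (nrow(amps) < 2) stop("need at least 2 time samples")
  mu <- colMeans(amps)
  colMeans(amps^2) - mu^2
}

#' Upper envelope of a signal
#'
#' Linear interpolation through the sliding-window local maxima: samples
#' that attain the maximum of their centered window are anchor points; the
#' envelope is constant-extrapolated beyond the outermost anchors.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param window envelope window in seconds (default 2, one slow breath).
#' @return numeric series of the same length, `>= x` at anchor points.
#' @export
upper_envelope <- function(x, fs, window = 2) {
  n <- length(x)
  w <- max(3L, 2L * floor(window * fs / 2) + 1L)  # odd, centered
  if (w > n) stop("envelope window longer than the series")
  rmax <- running_max(x, w)
  anchor <- which(x >= rmax - .Machine$double.eps * 16 * pmax(abs(rmax), 1))
  if (length(anchor) < 2) return(rep(x[anchor[1]], n))
  approx(anchor, x[anchor], xout = seq_len(n), rule = 2)$y
}

#' Per-subcarrier envelope deviation
#'
#' Mean absolute gap between the upper envelope and the signal. Sparse large
#' outliers drag the envelope far above the bulk of the samples, so a large
#' deviation flags an outlier-contaminated subcarrier.
#'
#' @inheritParams variance_scores
#' @param fs sampling rate in Hz; taken from the `amplitude_matrix`
#'   attribute when present.
#' @param window envelope window in seconds (default 2).
#' @return numeric vector, one mean deviation per subcarrier.
#' @export
envelope_deviation <- function(amps, fs = attr(amps, "fs"), window = 2) {
  if (is.null(fs)) stop("`fs` is required when `amps` carries no fs attribute")
  m <- as.matrix(amps)
  if (nrow(m) < 2 * max(3, round(window * fs)))
    stop("series too short for the envelope window")
  apply(m, 2, function(x) mean(abs(upper_envelope(x, fs, window) - x)))
}

#' Select the breathing-sensitive subcarrier by rank scoring
#'
#' Each subcarrier receives `K - rank + 1` points for variance (descending:
#' highest variance earns `K` points) and `K - rank + 1` points for envelope
#' deviation (ascending, after normalizing the deviation by the subcarrier's
#' standard deviation: the cleanest earns `K` points). The winner maximizes
#' the summed score; ties break to lower deviation, then to lower index.
#'
#' The deviation rank uses the scale-free ratio `mean|envelope - x| / sd(x)`
#' rather than the raw deviation: a clean quasi-sinusoid has ratio near 1.4
#' regardless of its amplitude, pure noise near 2.5, and spiky outlier
#' subcarriers far above that, so the ratio separates waveform quality from
#' waveform size (which the variance score already measures).
#'
#' @inheritParams envelope_deviation
#' @return list with `index` (1-based winning subcarrier) and `table`, a
#'   `data.frame` of class `subcarrier_score_table` with columns
#'   `subcarrier`, `variance`, `deviation`, `rel_deviation`,
#'   `variance_score`, `deviation_score`, `combined_score`, `rank`.
#' @export
select_subcarrier <- function(amps, fs = attr(amps, "fs"), window = 2) {
  m <- as.matrix(amps)
  K <- ncol(m)
  if (K < 2) stop("need at least 2 subcarriers")
  v <- variance_scores(m)
  if (all(v <= .Machine$double.eps * 100))
    stop("no breathing-sensitive subcarrier: all subcarriers are constant")
  dev <- envelope_deviation(m, fs = fs, window = window)
  s <- sqrt(v)
  rel <- ifelse(s > 0, dev / s, 0)

  # tie-aware ranks on values quantized to 10 significant digits, so that
  # subcarriers indistinguishable up to numerical noise score equal points
  # (e.g. noiseless channels, where every subcarrier is equally clean)
  var_rank <- rank(-signif(v, 10), ties.method = "min")  # 1 = highest variance
  dev_rank <- rank(signif(rel, 10), ties.method = "min") # 1 = cleanest
  variance_score <- K - var_rank + 1
  deviation_score <- K - dev_rank + 1
  combined <- variance_score + deviation_score

  ord <- order(-combined, rel, seq_len(K))
  rk <- integer(K)
  rk[ord] <- seq_len(K)

  tab <- data.frame(subcarrier = seq_len(K), variance = v, deviation = dev,
                    rel_deviation = rel,
                    variance_score = variance_score,
                    deviation_score = deviation_score,
                    combined_score = combined, rank = rk)
  class(tab) <- c("subcarrier_score_table", "data.frame")
  list(index = ord[1], table = tab)
}

#' @export
print.subcarrier_score_table <- function(x, ...) {
  cat("<subcarrier_score_table>\n")
  print.data.frame(head(x[order(x$rank), ], 10), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 10) cat(sprintf("... %d more subcarriers\n", nrow(x) - 10))
  invisible(x)
}
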