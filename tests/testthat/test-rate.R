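test_that("spectrogram geometry matches the window arithmetic", {
  x <- tone(0.25, 60, 50)
  sg <- stft_spectrogram(x, 50)
  expect_equal(ncol(sg$magnitude), 3000 - 512 + 1)  # 2489 frames
  r <- spectrogram_resolution(sg)
  expect_equal(r$time_ms, 20)
  expect_equal(r$freq_hz, 0.017)
  expect_equal(r$freq_hz_exact, 50 / 3000)
  expect_equal(diff(sg$freqs[1:2]), 50 / 3000)
  expect_error(stft_spectrogram(rnorm(100), 50), "shorter than one")
  expect_error(stft_spectrogram(x, 50, window = 512, overlap = 512),
               "smaller than")
})

test_that("dominant frequency finds pure tones to within one bin", {
  fs <- 50
  bin <- fs / 3000
  for (f in seq(0.1, 0.6, by = 0.05)) {
    for (ph in c(0, 1.1)) {
      x <- tone(f, 60, fs, phase = ph)
      est <- dominant_frequency(stft_spectrogram(x, fs))
      expect_lte(abs(est$hz - f), bin + 1e-9)
      expect_equal(est$breaths_per_min, 60 * est$hz)
    }
  }
  # degenerate: constant signal has no in-band peak
  expect_error(dominant_frequency(stft_spectrogram(rep(3, 3000), 50)),
               "no in-band peak")
  sg <- stft_spectrogram(tone(0.25, 60, 50), 50)
  expect_error(dominant_frequency(sg, band = c(30, 40)), "empty band")
})

test_that("breath counting matches the schedule and handles flat signals", {
  w <- generate_waveform("normal", 60, 50, rate_bpm = 15, seed = 1)
  bc <- count_breaths(w$displacement, 50)
  expect_equal(bc$count, 15)
  expect_equal(bc$rate$hz, 0.25)
  expect_equal(bc$rate$breaths_per_min, 15)

  flat <- count_breaths(rep(1, 1000), 50)
  expect_equal(flat$count, 0)
  expect_true(is.na(flat$rate$hz))
  expect_error(count_breaths(rnorm(100), 50), "10 s")
})

test_that("a trailing unpaired inhale counts as half a breath", {
  fs <- 50
  # 4 full breaths (4 s each) then a final rise cut off mid-inhale
  full <- rep(0.5 * (1 - cos(2 * pi * (0:199) / 200)), 4)
  half <- 0.5 * (1 - cos(2 * pi * (0:99) / 200))   # rising half-cycle
  x <- c(full, half)
  bc <- count_breaths(x, fs)
  expect_equal(bc$count, 4.5)
})

test_that("breath counts convert to the conventional printed rates", {
  r <- breaths_to_rate(18.5, 110)
  expect_equal(round(r$hz, 2), 0.17)
  expect_equal(round(rate_estimate(0.26, "stft")$breaths_per_min, 1), 15.6)
  expect_equal(rate_estimate(0.25, "stft")$breaths_per_min, 15)
})

test_that("STFT and peak counting agree on periodic patterns", {
  for (pat in c("normal", "kussmaul")) {
    w <- generate_waveform(pat, 60, 50, seed = 2)
    sg <- stft_spectrogram(w$displacement, 50)
    f_stft <- dominant_frequency(sg)$hz
    f_peak <- count_breaths(w$displacement, 50)$rate$hz
    expect_lt(abs(f_stft - f_peak) / f_peak, 0.10)
  }
})

test_that("STFT over-reads the rate of aperiodic Biot's breathing", {
  # the spectrogram tracks the within-burst breath frequency while the
  # breath count averages over the apneas, so the two must disagree
  w <- generate_waveform("biots", 110, 50, seed = 3)
  f_stft <- dominant_frequency(stft_spectrogram(w$displacement, 50))$hz
  f_peak <- count_breaths(w$displacement, 50)$rate$hz
  expect_gt(f_stft, f_peak * 1.2)
})

test_that("scheduled apneas are detected with high overlap, and only those", {
  hits <- 0
  for (s in 1:20) {
    w <- generate_waveform("biots", 110, 50, seed = s)
    sg <- stft_spectrogram(w$displacement, 50)
    ap <- detect_apneas(sg)
    ok <- nrow(ap) == 3 &&
      all(vapply(seq_len(3), function(i)
        interval_overlap(ap$start[i], ap$end[i], w$apnea_intervals[[i]]),
        numeric(1)) >= 0.8)
    hits <- hits + ok
  }
  expect_equal(hits, 20)  # recall and precision 1.0 on noiseless records

  # continuous breathing yields no apneas
  wn <- generate_waveform("normal", 60, 50, seed = 1)
  expect_equal(nrow(detect_apneas(stft_spectrogram(wn$displacement, 50))), 0)

  # an all-zero record is one record-long apnea
  ap0 <- detect_apneas(stft_spectrogram(rep(0, 3000), 50))
  expect_equal(ap0, data.frame(start = 0, end = 60))
})

test_that("sighs are flagged at their scheduled times", {
  w <- generate_waveform("sighing", 60, 50, sigh_ratio = 1.8, seed = 5)
  sighs <- detect_sighs(w$displacement, 50)
  expect_length(sighs, 5)
  for (s in w$sigh_times)
    expect_true(any(abs(sighs - s) <= 1.5))

  # uniform breathing has no sighs
  wn <- generate_waveform("normal", 60, 50, seed = 1)
  expect_length(detect_sighs(wn$displacement, 50), 0)

  # one doubled breath among ten is exactly the flagged one
  fs <- 50
  breath <- 0.5 * (1 - cos(2 * pi * (0:199) / 200))
  x <- c(rep(breath, 5), 2 * breath, rep(breath, 4))
  s1 <- detect_sighs(x, fs)
  expect_length(s1, 1)
  expect_equal(s1, 5 * 4 + 2, tolerance = 0.05)  # peak of the 6th breath

  expect_error(detect_sighs(breath, fs), "too few breaths")
})
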