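test_that("a normal waveform has exactly the scheduled number of breaths", {
  w <- generate_waveform("normal", duration = 60, fs = 50, rate_bpm = 15,
                         seed = 1)
  expect_length(w$displacement, 3000)
  x <- w$displacement
  peaks <- which(diff(sign(diff(x))) == -2) + 1
  peaks <- peaks[x[peaks] > 0.5 * w$depth]
  expect_equal(length(peaks), 15)

  # mean breath-to-breath period matches 60 / rate within one sample
  expect_equal(mean(diff(peaks)) / 50, 4, tolerance = 1 / 50 / 4)
})

test_that("Biot's apneas are near-silent relative to breathing segments", {
  w <- generate_waveform("biots", duration = 110, fs = 50, seed = 2)
  sched <- list(c(20, 30), c(55, 65), c(95, 105))
  expect_equal(w$apnea_intervals, sched)
  x <- w$displacement
  idx <- rep(FALSE, length(x))
  tt <- (seq_along(x) - 1) / 50
  for (iv in sched) idx <- idx | (tt >= iv[1] & tt < iv[2])
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(x[idx]), 0.1 * rms(x[!idx]))
})

test_that("sigh breaths scale within the physiological 1.5-2x band", {
  w <- generate_waveform("sighing", duration = 60, fs = 50,
                         sigh_ratio = 1.8, seed = 3)
  expect_equal(w$sigh_times, c(10, 22, 35, 47, 58))
  x <- w$displacement
  peaks <- which(diff(sign(diff(x))) == -2) + 1
  heights <- x[peaks]
  med <- median(heights)
  for (s in w$sigh_times) {
    near <- peaks[abs((peaks - 1) / 50 - s) < 2.5]
    expect_true(length(near) >= 1)
    expect_gte(max(x[near]), 1.5 * med)
    expect_lte(max(x[near]), 2.1 * med)
  }
  expect_warning(generate_waveform("sighing", 60, 50, sigh_ratio = 2.5,
                                   seed = 1), "physiological")
})

test_that("waveform randomness is seed-reproducible", {
  a <- generate_waveform("ataxic", 60, 50, seed = 9)
  b <- generate_waveform("ataxic", 60, 50, seed = 9)
  c <- generate_waveform("ataxic", 60, 50, seed = 10)
  expect_identical(a$displacement, b$displacement)
  expect_false(identical(a$displacement, c$displacement))
})

test_that("scheduled events are recoverable from the noiseless displacement", {
  # every scheduled apnea is flat, every scheduled sigh is tall
  for (pat in c("biots", "cheyne_stokes")) {
    w <- generate_waveform(pat, 110, 50, seed = 4)
    tt <- (seq_along(w$displacement) - 1) / 50
    for (iv in w$apnea_intervals) {
      inside <- w$displacement[tt >= iv[1] + 0.5 & tt < iv[2] - 0.5]
      expect_lt(max(abs(inside)), 0.06 * w$depth)
    }
  }
})

test_that("the apnea schedule is validated", {
  expect_error(generate_waveform("biots", 60, 50, seed = 1),
               "exceeds the record duration")
  expect_error(
    generate_waveform("biots", 110, 50, seed = 1,
                      apnea_intervals = list(c(10, 30), c(20, 40))),
    "overlap")
})

test_that("simulated CSI has the right shape and an exact affine planted channel", {
  w <- generate_waveform("normal", 60, 50, seed = 1)
  ch <- channel_params(noise_sd = 0, outlier_rate = 0, sensor_noise_sd = 0,
                       seed = 5)
  sim <- simulate_csi(w, ch, antennas = 3)
  expect_equal(dim(sim$csi$values), c(3000, 3, 30))
  amp <- amplitude(sim$csi, 2)
  # noiseless planted subcarrier is an affine map of displacement
  expect_equal(abs(cor(amp[, ch$planted], w$displacement)), 1,
               tolerance = 1e-12)
  expect_equal(sim$reference, w$displacement)
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  w <- generate_waveform("normal", 20, 50, seed = 1)
  s1 <- simulate_csi(w, channel_params(seed = 3), antennas = 2)
  s2 <- simulate_csi(w, channel_params(seed = 3), antennas = 2)
  s3 <- simulate_csi(w, channel_params(seed = 4), antennas = 2)
  expect_identical(s1$csi$values, s2$csi$values)
  expect_identical(s1$reference, s2$reference)
  expect_false(identical(s1$csi$values, s3$csi$values))
})

test_that("channel parameters enforce a planted sensitive subcarrier", {
  expect_error(channel_params(sensitivity = rep(1, 30)),
               "planted breathing-sensitive")
  ch <- channel_params(seed = 2)
  expect_gte(max(ch$sensitivity), 3 * median(ch$sensitivity))
})
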