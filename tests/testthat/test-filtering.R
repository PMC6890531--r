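test_that("the sym8 decomposition matches an independently computed reference", {
  # single-level DWT of (1:20)^1.5, reference computed with an independent
  # wavelet implementation (symmetric extension) and frozen here
  x <- (1:20)^1.5
  s <- csibreathe:::dwt_step(x)
  a_ref <- c(21.607655431886784, 12.085881228524881, 4.130091968971769,
             1.4674014433468223, 6.849856825950819, 15.026672721843783,
             25.306198268389927, 37.17025747398939, 50.47208854774439,
             65.06565815242764, 80.91779490650953, 97.20917119864689,
             117.50145939289747, 125.90534910876232, 109.08839553278216,
             92.0724019583151, 75.32015595701078)
  d_ref <- c(-6.5585479901806853e-03, 4.2526924239892183e-02,
             -9.9677615848991027e-02, 2.6140425373325316e-01,
             -2.6679250185520798e-01, 7.9673685251792026e-02,
             -1.0227051989218800e-02, -1.6759123149735289e-04,
             -2.5762405886038675e-05, -6.6281160704187436e-06,
             4.0553435873028829e-02, -2.3042597523568972e-01,
             5.0579310085395335e-01, -1.4042235618192231e+00,
             1.4748376971015595e+00, -4.5175838200468826e-01,
             6.5216380335562152e-02)
  expect_equal(s$a, a_ref, tolerance = 1e-9)
  expect_equal(s$d, d_ref, tolerance = 1e-7)
})

test_that("multilevel decomposition reconstructs perfectly", {
  set.seed(10)
  for (n in c(64, 317, 1000)) {
    x <- cumsum(rnorm(n))
    dec <- csibreathe:::wavedec_sym8(x, 4)
    expect_equal(csibreathe:::waverec_sym8(dec), x, tolerance = 1e-9)
  }
})

test_that("the SURE threshold minimizes the brute-force risk", {
  set.seed(11)
  x <- c(rnorm(200), rnorm(10, sd = 6))
  thr <- csibreathe:::sure_threshold(x)
  # independent oracle: evaluate the SURE risk at every candidate threshold
  risk <- function(t) {
    n <- length(x)
    (n - 2 * sum(abs(x) <= t) + sum(pmin(x^2, t^2))) / n
  }
  risks <- vapply(sort(abs(x)), risk, numeric(1))
  expect_equal(risk(thr), min(risks), tolerance = 1e-12)
  # heuristic: sparse coefficients fall back to the universal threshold
  sparse <- c(rep(1e-4, 255), 0.5)
  expect_equal(csibreathe:::heursure_threshold(sparse),
               sqrt(2 * log(256)))
})

test_that("wavelet denoising leaves constants alone and removes spikes", {
  expect_equal(wavelet_denoise(rep(2.5, 300)), rep(2.5, 300),
               tolerance = 1e-9)

  fs <- 50
  t <- (0:(fs * 40 - 1)) / fs
  clean <- sin(2 * pi * 0.25 * t)
  set.seed(12)
  noisy <- clean
  noisy[sample(length(t), 10)] <- noisy[sample(length(t), 10)] + 5
  den <- wavelet_denoise(noisy)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(den, clean), rmse(noisy, clean))

  expect_error(wavelet_denoise(rnorm(10)), "too short")
})

test_that("denoising pure noise does not inflate the variance", {
  for (s in 1:20) {
    set.seed(100 + s)
    x <- rnorm(500)
    expect_lte(var(wavelet_denoise(x)), var(x))
  }
})

test_that("denoising preserves the dominant frequency of a breathing tone", {
  fs <- 50
  for (f in c(0.15, 0.25, 0.45)) {
    set.seed(13)
    x <- tone(f, 60, fs) + rnorm(60 * fs, sd = 0.3)
    before <- dominant_frequency(stft_spectrogram(x, fs))$hz
    after <- dominant_frequency(stft_spectrogram(wavelet_denoise(x), fs))$hz
    expect_equal(after, before)
  }
})

test_that("moving_average matches a brute-force sliding mean", {
  expect_equal(moving_average(c(5, 1, 9), 1), c(5, 1, 9))
  alt <- rep(c(1, -1), 10)
  expect_true(all(moving_average(alt, 2)[1:19] == 0))

  set.seed(14)
  x <- rnorm(101)
  for (w in c(2, 5, 10)) {
    got <- moving_average(x, w)
    h1 <- (w - 1) %/% 2
    h2 <- w - 1 - h1
    oracle <- vapply(seq_along(x), function(i)
      mean(x[max(1, i - h1):min(length(x), i + h2)]), numeric(1))
    expect_equal(got, oracle)
  }
  expect_error(moving_average(x, 0), "positive")
  # smoothing never increases the variance
  for (s in 1:10) {
    set.seed(200 + s)
    y <- rnorm(400)
    expect_lte(var(moving_average(y, 25)), var(y))
  }
})

test_that("both filters preserve length and pass constants through", {
  x <- rnorm(333)
  expect_length(wavelet_denoise(x), 333)
  expect_length(moving_average(x, 7), 333)
  expect_equal(moving_average(rep(4, 50), 10), rep(4, 50))
  expect_length(filter_signal(x, fs = 50), 333)
})
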