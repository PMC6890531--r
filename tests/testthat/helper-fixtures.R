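# Shared fixtures, built in code at test time.

# CFR series with prescribed amplitude and phase arrays.
make_cfr <- function(amp, ph, fs = 50) {
  cfr_series(amp * exp(1i * ph), fs = fs)
}

# Random complex CFR series.
random_cfr <- function(n = 100, antennas = 2, subcarriers = 5, fs = 50,
                       seed = 42) {
  set.seed(seed)
  v <- array(complex(real = rnorm(n * antennas * subcarriers),
                     imaginary = rnorm(n * antennas * subcarriers)),
             dim = c(n, antennas, subcarriers))
  cfr_series(v, fs = fs)
}

# Pure tone sampled at fs.
tone <- function(freq, duration, fs = 50, phase = 0, amp = 1) {
  amp * sin(2 * pi * freq * (0:(duration * fs - 1)) / fs + phase)
}

# Fraction of a scheduled interval covered by a detected interval.
interval_overlap <- function(det_start, det_end, sched) {
  max(0, min(det_end, sched[2]) - max(det_start, sched[1])) /
    (sched[2] - sched[1])
}
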