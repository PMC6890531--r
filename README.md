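# csibreathe

Non-invasive respiratory monitoring from WiFi-class channel state
information (CSI), in R.

A person breathing near a radio link perturbs its multipath geometry: the
rise and fall of the chest modulates the amplitude `||H(f_k)||` of each
OFDM subcarrier's channel frequency response, packet by packet. From a
50 Hz stream of complex CFR packets (3 receive antennas x 30 subcarriers),
`csibreathe` recovers the breathing waveform and reads off the respiratory
rate and respiratory events — without any sensor on the body. It is aimed
at researchers in RF sensing and physiological monitoring who need a
complete, reproducible reference pipeline plus a simulator to test against.

The pipeline:

1. **Subcarrier selection** — each subcarrier is scored on amplitude
   variance (breathing sensitivity) and on the mean gap between its upper
   envelope and the signal (outlier contamination); the best rank-sum wins.
2. **Filtering** — sym8 wavelet denoising (level 4, soft heuristic-SURE
   thresholding, noise scale from the finest detail level) followed by a
   1-s moving average.
3. **Rate extraction** — STFT spectrogram (Hamming 512 / overlap 511 /
   nfft 3000 at 50 Hz: 20 ms and 0.017 Hz resolution); the respiratory
   rate is the dominant frequency in 0.05–1 Hz, cross-checked by
   prominence-based breath-peak counting. Apneas are read from in-band
   spectral power dips, sighs from outsized breath peaks.
4. **Evaluation** — wireless and contact-sensor traces are normalized to
   [−1, 1] (`x' = a + (x − x_min)/(x_max − x_min)·(b − a)`) and compared by
   `MSE = (1/n) Σ (X̂_i − X_i)²` and Pearson's
   `ρ = cov(X, Y)/(σ_X σ_Y)`.

A seeded simulator generates ground-truth chest-displacement waveforms for
six breathing patterns — normal, Biot's, Cheyne-Stokes, ataxic, Kussmaul,
sighing — and the CSI records they would produce (heterogeneous subcarrier
sensitivity, Gaussian noise, outlier bursts), standing in for experimental
recordings that are not publicly available.

## Worked example

```r
library(csibreathe)

w   <- generate_waveform("normal", duration = 60, fs = 50, rate_bpm = 15,
                         seed = 1)
sim <- simulate_csi(w, channel_params(seed = 7), antennas = 3)
res <- run_pipeline(sim$csi, sim$reference)
res
#> <pipeline_result>
#>   selected subcarrier: 14
#>   STFT rate: 0.25 Hz (15.0 breaths/min)
#>   peak-count rate: 0.25 Hz (15 breaths / 60 s)
#>   apneas: 0, sighs: 0
#>   agreement: MSE 0.0048, CC 0.9945
```

The scoring picked the breathing-sensitive subcarrier (the simulator
plants subcarrier 14); both rate estimators read the scheduled
15 breaths/min (0.25 Hz); no apneas or sighs were scheduled and none were
detected; and after range normalization the recovered waveform matches the
simulated contact sensor with MSE 0.005 and correlation 0.994.

An abnormal pattern:

```r
wb   <- generate_waveform("biots", duration = 110, fs = 50, seed = 2)
resb <- run_pipeline(simulate_csi(wb, channel_params(seed = 2))$csi)
resb$apneas
#>   start    end
#> 1 20.45  29.53
#> 2 54.43  64.55
#> 3 93.45 103.87
```

— the three scheduled breathing pauses (20–30 s, 55–65 s, 95–105 s),
localized from the spectrogram's in-band power.

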