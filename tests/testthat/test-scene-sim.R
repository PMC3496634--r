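test_that("geometry validates and derives the 1.297-sample inter-mic delay", {
  expect_equal(delay_samples(array_geometry()), 1.297, tolerance = 5e-4)
  expect_error(array_geometry(mic_spacing_m = 0), "positive")
  g <- array_geometry(0.02, 340, 48000)
  expect_equal(delay_samples(g), 0.02 / 340 * 48000)
})

test_that("speech-like synthesis is seeded, band-limited and validated", {
  a <- synth_speech_like(1, 120, seed = 7)
  b <- synth_speech_like(1, 120, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_length(a$samples, 44100)
  expect_lte(max(abs(a$samples)), 1)

  # spectral energy above 6 kHz at least 40 dB below the strongest harmonic
  spec <- Mod(stats::fft(a$samples * signal::hanning(length(a$samples))))^2
  f <- (seq_along(spec) - 1) * 44100 / length(spec)
  half <- f <= 22050
  peak <- max(spec[half])
  expect_lt(10 * log10(max(spec[half & f > 6000]) / peak), -40)

  expect_error(synth_speech_like(0, 120), "duration")
  expect_error(synth_speech_like(1, 30), "f0")
})

test_that("noise kinds have the advertised statistical structure", {
  w <- synth_noise(1, "white", seed = 3)
  expect_identical(w$samples, synth_noise(1, "white", seed = 3)$samples)
  ac <- stats::acf(w$samples, lag.max = 100, plot = FALSE)$acf
  expect_lt(abs(ac[101]), 0.05)

  m <- synth_noise(2, "tonal_music", seed = 3)
  fe <- vapply(split(m$samples[1:88000], rep(1:100, each = 880)),
               function(b) mean(b^2), numeric(1))
  fe <- fe[fe > 0]
  expect_gt(10 * log10(max(fe) / min(fe)), 6)

  expect_error(synth_noise(1, "pink"), "arg")
  expect_error(synth_noise(-1, "white"), "duration")
})

test_that("azimuth delay rendering matches the plane-wave model", {
  src <- synth_noise(0.5, "white", seed = 5)
  g <- default_geom

  # 90 degrees: zero delay, channels identical
  p90 <- apply_azimuth_delay(src, 90, g)
  expect_equal(p90$at_mic2$samples, p90$at_mic1$samples, tolerance = 1e-9)

  # 0 degrees: 1.297 samples recovered by interpolated cross-correlation
  p0 <- apply_azimuth_delay(src, 0, g)
  idx <- 200:21800
  lag0 <- xcorr_delay(p0$at_mic1$samples[idx], p0$at_mic2$samples[idx])
  expect_lt(abs(lag0 - 1.297), 0.02)

  # 180 degrees: equal magnitude, opposite sign
  p180 <- apply_azimuth_delay(src, 180, g)
  lag180 <- xcorr_delay(p180$at_mic1$samples[idx], p180$at_mic2$samples[idx])
  expect_lt(abs(lag180 + lag0), 0.02)

  # pure delay preserves energy (measured in the interpolator's flat band;
  # the windowed sinc rolls off only near Nyquist)
  e1 <- band_rms(p0$at_mic1$samples, lo = 100, hi = 15000)^2
  e2 <- band_rms(p0$at_mic2$samples, lo = 100, hi = 15000)^2
  expect_equal(e2, e1, tolerance = 1e-3)
  expect_error(apply_azimuth_delay(audio(numeric(0)), 0, g), "empty")
})

test_that("simulate_scene mixes at the requested SNR with exact superposition", {
  scene <- make_scene(seed = 2, lead_in_s = 0.5)
  m <- scene$segment_marks
  expect_equal(unname(m["speech_start"]), round(0.5 * 44100))

  # superposition at mic 1 is exact
  expect_equal(scene$mic1$samples,
               scene$speech_mic1$samples + scene$noise_mic1$samples)
  expect_equal(scene$mic2$samples,
               scene$speech_mic2$samples + scene$noise_mic2$samples)

  # 0 dB over the speech-active region at mic 1, within 0.1 dB
  reg <- (m["speech_start"] + 1):m["speech_end"]
  got <- 10 * log10(sum(scene$speech_mic1$samples[reg]^2) /
                      sum(scene$noise_mic1$samples[reg]^2))
  expect_lt(abs(got - 0), 0.1)

  # determinism
  scene2 <- make_scene(seed = 2, lead_in_s = 0.5)
  expect_identical(scene$mic1$samples, scene2$mic1$samples)
  expect_identical(scene$mic2$samples, scene2$mic2$samples)

  expect_error(
    simulate_scene(synth_speech_like(1, 120, seed = 1), source_spec(0),
                   synth_noise(0.5, "white", seed = 1), source_spec(90),
                   default_geom, 0, 1, 0.5),
    "cover the whole session")
})

test_that("a moving interferer sweeps its inter-mic delay monotonically along the trajectory", {
  nz <- synth_noise(1.4, "white", seed = 9)
  traj <- data.frame(time_s = c(0, 1), azimuth_deg = c(75, 105))
  scene <- simulate_scene(synth_speech_like(0.1, 120, seed = 1),
                          source_spec(0), nz,
                          source_spec(75, traj), default_geom,
                          snr_db = 0, lead_in_s = 0.45, tail_s = 0.45)
  n1 <- scene$noise_mic1$samples
  n2 <- scene$noise_mic2$samples
  fs <- 44100
  blocks <- seq(0.05, 0.95, by = 0.15)
  lags <- vapply(blocks, function(t0) {
    idx <- round(t0 * fs):round((t0 + 0.05) * fs)
    xcorr_delay(n1[idx], n2[idx], max_lag = 4)
  }, numeric(1))
  d <- delay_samples(default_geom)
  expect_true(all(diff(lags) < 0))  # cos(azimuth) decreases over 75 -> 105
  az_expected <- 75 + 30 * (blocks + 0.025)   # trajectory at window centers
  expect_lt(max(abs(lags - d * cos(az_expected * pi / 180))), 0.08)
})
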