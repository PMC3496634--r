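test_that("magnitude estimator recovers a noise-free front tone and floors negatives", {
  g <- default_geom
  fs <- g$sample_rate_hz
  freqs <- (0:512) * fs / 1024
  dc <- 0.01 / 340

  # noise-free front speech: per-bin ch1 power 4 sin^2(w d/c) |S|^2, ch2 zero
  S <- numeric(513); S[24] <- 3   # a tone near 1 kHz with magnitude 3
  p1 <- (2 * sin(2 * pi * freqs * dc))^2 * S^2
  est <- estimate_speech_magnitude(p1, numeric(513), 0, g, freqs)
  expect_lt(abs(est[24] / 3 - 1), 0.02)

  # a bin where ratio * ch2 exceeds ch1 floors to zero without error
  est2 <- estimate_speech_magnitude(c(1, 1), c(1, 10), 2, g, freqs[c(10, 20)])
  expect_equal(est2[2], 0)
  expect_true(all(est2 >= 0))
})

test_that("two-tone scene: noise bin suppressed, speech bin preserved (closed-form powers)", {
  g <- default_geom
  fs <- g$sample_rate_hz
  freqs <- (0:512) * fs / 1024
  dc <- 0.01 / 340
  b_sp <- 24   # ~1 kHz speech tone, front
  b_nz <- 47   # ~2 kHz noise tone, 90 degrees
  A2 <- function(f, cphi) abs(exp(-2i * pi * f * dc * cphi) - exp(-2i * pi * f * dc))^2
  A1 <- function(f, cphi) abs(1 - exp(-2i * pi * f * dc * (1 + cphi)))^2
  S <- 2; N <- 2 * S * sqrt(A1(freqs[b_sp], 1) / A1(freqs[b_nz], 0))  # equal ch1 power

  p1 <- numeric(513); p2 <- numeric(513)
  p1[b_sp] <- A1(freqs[b_sp], 1) * S^2; p1[b_nz] <- A1(freqs[b_nz], 0) * N^2
  p2[b_sp] <- A2(freqs[b_sp], 1) * S^2; p2[b_nz] <- A2(freqs[b_nz], 0) * N^2
  ratio <- A1(freqs, 0) / pmax(A2(freqs, 0), 1e-12)   # noise directivity per bin

  est <- estimate_speech_magnitude(p1, p2, ratio, g, freqs)
  unsub <- estimate_speech_magnitude(p1, numeric(513), 0, g, freqs)
  expect_lt(20 * log10((est[b_nz] + 1e-12) / unsub[b_nz]), -20)
  expect_lt(abs(20 * log10(est[b_sp] / S)), 3)
})

test_that("clean front speech passes through the full pipeline within 3 dB band-limited spectral RMS", {
  sp <- synth_speech_like(1.2, 120, seed = 7)
  pair <- apply_azimuth_delay(sp, 0, default_geom)
  n_lead <- round(0.5 * 44100)
  m1 <- c(numeric(n_lead), pair$at_mic1$samples, numeric(4410))
  m2 <- c(numeric(n_lead), pair$at_mic2$samples, numeric(4410))
  fit <- enhance(list(mic1 = m1, mic2 = m2), fs = 44100)
  ref <- c(numeric(n_lead), sp$samples, numeric(4410))
  Pr <- rowMeans(stft(audio(ref))$power)
  Po <- rowMeans(stft(fit$output)$power)
  f <- (0:512) * 44100 / 1024
  sel <- f >= 156 & f <= 5498 & Pr > 0
  dev_db <- 10 * log10(Po[sel] / Pr[sel])
  weighted_rms <- sqrt(sum(Pr[sel] * dev_db^2) / sum(Pr[sel]))
  expect_lt(weighted_rms, 3)
})

test_that("enhancement output is finite for degenerate inputs", {
  fs <- 44100
  n <- 3 * fs / 2
  inputs <- list(
    zero = numeric(n),
    dc = rep(0.5, n),
    nyquist = rep_len(c(1, -1), n) * 0.5)
  for (nm in names(inputs)) {
    x <- inputs[[nm]]
    fit <- enhance(list(mic1 = x, mic2 = x), fs = fs)
    expect_true(all(is.finite(fit$output$samples)), info = nm)
  }
  # a real scene also stays finite
  scene <- make_scene(seed = 5)
  fit <- enhance(scene)
  expect_true(all(is.finite(fit$output$samples)))
  expect_true(all(is.finite(fit$gain)))
})

test_that("a session without a noise lead-in warns and passes channel 1 through", {
  x <- synth_speech_like(0.12, 120, seed = 2)$samples
  expect_warning(fit <- enhance(list(mic1 = x, mic2 = x), fs = 44100),
                 "no noise-only lead-in")
  expect_true(all(is.finite(fit$output$samples)))
})

test_that("raising the noise azimuth from 60 to 180 degrees does not degrade median SNR gain", {
  dsnr <- function(naz) {
    stats::median(vapply(1:2, function(s) {
      scene <- make_scene("babble", noise_az = naz, seed = s, lead_in_s = 1,
                          tail_s = 0.5)
      fit <- enhance(scene)
      p <- shadow_decompose(fit, scene)
      delta_snr(scene, p$s_hat, p$n_hat, bands = FALSE)$delta_snr_db
    }, numeric(1)))
  }
  d60 <- dsnr(60); d120 <- dsnr(120); d180 <- dsnr(180)
  expect_gt(d120, d60 - 2)    # allow sampling noise, trend must hold
  expect_gt(d180, d120 - 2)
  expect_gt(d180, d60)
})

test_that("enhance object prints, summarizes and serializes diagnostics", {
  scene <- make_scene(seed = 3, lead_in_s = 0.6, speech_s = 0.6)
  fit <- enhance(scene)
  expect_output(print(fit), "dcse_enhance")
  s <- summary(fit)
  expect_output(print(s), "directivity")
  expect_true(s$n_noise_frames > 0)
  path <- tempfile(fileext = ".json")
  write_diagnostics_json(fit, path)
  diag <- jsonlite::read_json(path)
  expect_equal(length(diag$noise_only), length(fit$labels$noise_only))
})
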