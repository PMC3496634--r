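test_that("snr_db computes energy ratios with edge handling", {
  expect_equal(snr_db(c(1, 1), c(1, 1)), 0)
  expect_equal(snr_db(c(10, 0), c(1, 0)), 20)
  expect_equal(snr_db(c(1, 0), c(0, 2)), 10 * log10(1 / 4))   # -6.02
  expect_warning(v <- snr_db(c(1, 1), c(0, 0)), "infinite")
  expect_identical(v, Inf)
  expect_error(snr_db(1:3, 1:2), "equal length")
})

test_that("shadow decomposition is exact for masks and additive for the real pipeline", {
  scene <- make_scene(seed = 4, lead_in_s = 0.6, speech_s = 0.8)
  fit <- enhance(scene)

  # identity mask returns the channel-domain references themselves
  fit_id <- fit
  fit_id$gain <- matrix(1, nrow(fit$gain), ncol(fit$gain))
  parts_id <- shadow_decompose(fit_id, scene)
  duo_s <- form_channels(scene$speech_mic1, scene$speech_mic2, fit$geom,
                         fit$delay_filter)
  ref <- istft_overlap_add(stft(duo_s$ch1, fit$frame))$samples
  expect_equal(parts_id$s_hat$samples, ref, tolerance = 1e-9)

  # global 0.5 mask halves both components
  fit_half <- fit
  fit_half$gain <- fit_id$gain * 0.5
  parts_half <- shadow_decompose(fit_half, scene)
  expect_equal(parts_half$s_hat$samples, ref * 0.5, tolerance = 1e-9)

  # real mask: s_hat + n_hat reconstructs the enhanced output
  parts <- shadow_decompose(fit, scene)
  resid <- parts$s_hat$samples + parts$n_hat$samples - fit$output$samples
  expect_lt(sqrt(mean(resid^2)) / sqrt(mean(fit$output$samples^2)), 1e-3)
})

test_that("delta_snr reports zero for an identity pipeline and +20 dB for ten-fold noise reduction", {
  scene <- make_scene(seed = 6, lead_in_s = 0.5, speech_s = 0.6)
  rep0 <- delta_snr(scene, scene$speech_mic1, scene$noise_mic1, bands = FALSE)
  expect_lt(abs(rep0$delta_snr_db), 0.1)

  n_tenth <- audio(scene$noise_mic1$samples * 0.1, 44100)
  rep20 <- delta_snr(scene, scene$speech_mic1, n_tenth, bands = FALSE)
  expect_equal(rep20$delta_snr_db, 20, tolerance = 1e-9)
})

test_that("uniform band weights over the CI bank approximate the broadband improvement", {
  scene <- make_scene(seed = 8, lead_in_s = 1, speech_s = 1)
  fit <- enhance(scene)
  parts <- shadow_decompose(fit, scene)
  rep <- delta_snr(scene, parts$s_hat, parts$n_hat)
  expect_length(rep$snr_band_in_db, 16)
  expect_equal(sum(rep$band_weights), 1)
  expect_true(is.finite(rep$delta_snr_weighted_db))
  # one full-range band with weight 1 reduces to the broadband measure
  wide <- data.frame(channel = 1, lo_hz = 20, hi_hz = 21000,
                     center_hz = 1000, coeff = 1)
  class(wide) <- c("band_table", "data.frame")
  rep1 <- delta_snr(scene, parts$s_hat, parts$n_hat,
                    band_weights = 1, table = wide)
  expect_lt(abs(rep1$delta_snr_weighted_db - rep1$delta_snr_db), 0.2)
  expect_error(delta_snr(scene, parts$s_hat, parts$n_hat,
                         band_weights = rep(1, 16)), "sum to 1")
})

test_that("distortion index matches its closed-form scalar-gain cases", {
  clean <- synth_speech_like(0.8, 120, seed = 10)
  expect_equal(distortion_index(clean, clean), -60)
  half <- audio(clean$samples * 0.5, 44100)
  expect_equal(distortion_index(clean, half), 10 * log10(0.25),
               tolerance = 1e-6)
  zero <- audio(numeric(length(clean)), 44100)
  expect_equal(distortion_index(clean, zero), 0)
  expect_error(distortion_index(zero, clean), "silent")

  # scale consistency: gain g shifts every per-bin gain to g * h
  g <- 0.8
  scaled <- audio(clean$samples * g, 44100)
  expect_equal(distortion_index(clean, scaled), 10 * log10((1 - g)^2),
               tolerance = 1e-6)
})

test_that("CIS vocoding shrinks the distortion between clean and enhanced speech", {
  scene <- make_scene(seed = 4, lead_in_s = 1, speech_s = 1, tail_s = 0.5)
  fit <- enhance(scene)
  active <- NULL
  di_raw <- distortion_index(scene$speech_mic1, fit$output)
  di_voc <- distortion_index(vocode(scene$speech_mic1), vocode(fit$output))
  expect_lt(di_voc, di_raw)
})
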