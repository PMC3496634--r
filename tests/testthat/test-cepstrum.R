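test_that("identical consecutive frames have zero cepstral distance", {
  p <- abs(stats::rnorm(513))^2 + 0.1
  tr <- cepstral_tracker()
  r1 <- update_cepstrum(tr, p)
  r2 <- update_cepstrum(r1$tracker, p)
  expect_equal(r2$distance, 0, tolerance = 1e-20)
  expect_false(r2$silent)
})

test_that("default configuration carries the published smoothing weight", {
  tr <- cepstral_tracker()
  expect_equal(tr$beta, 0.85)
  expect_error(cepstral_tracker(beta = 1), "beta")
  expect_error(cepstral_tracker(p = 0), "p must")
  expect_error(cepstral_tracker(threshold = -1), "threshold")
})

test_that("a tonal frame is far from a white-noise template, by an independent oracle", {
  # independent oracle: log power spectrum -> inverse DFT by direct summation
  oracle_cep <- function(pw, p) {
    lg <- log(pmax(pw, max(pw) * 1e-12))
    full <- c(lg, lg[(length(lg) - 1):2])
    N <- length(full)
    vapply(0:p, function(n) {
      Re(sum(full * exp(2i * pi * n * (0:(N - 1)) / N))) / N
    }, numeric(1))
  }
  set.seed(1)
  white1 <- abs(stats::rnorm(513, sd = 1))^2 + 1e-3
  white2 <- abs(stats::rnorm(513, sd = 1))^2 + 1e-3
  tone <- rep(1e-6, 513); tone[24] <- 100

  d <- function(a, b) {
    ca <- oracle_cep(a, 12); cb <- oracle_cep(b, 12)
    (ca[1] - cb[1])^2 + 2 * sum((ca[-1] - cb[-1])^2)
  }
  expect_gt(d(white1, tone) / d(white1, white2), 5)

  # package distances agree with the oracle construction
  tr <- cepstral_tracker()
  r1 <- update_cepstrum(tr, white1)
  r_tone <- update_cepstrum(r1$tracker, tone)
  r_white <- update_cepstrum(r1$tracker, white2)
  expect_gt(r_tone$distance / r_white$distance, 5)
  expect_equal(r_white$distance, d(white1, white2), tolerance = 1e-8)
})

test_that("silent frames are flagged and leave the tracker unchanged", {
  tr <- cepstral_tracker()
  tr <- update_cepstrum(tr, abs(stats::rnorm(513)) + 0.5)$tracker
  r <- update_cepstrum(tr, numeric(513))
  expect_true(r$silent)
  expect_equal(r$distance, 0)
  expect_identical(r$tracker$cepstrum, tr$cepstrum)
  expect_error(update_cepstrum(tr, c(-1, rep(1, 512))), "non-negative")
})

test_that("frame classification separates lead-in noise from speech at 0 dB", {
  # stationary-noise interferer: the regime the cepstral detector assumes
  fracs <- vapply(1:3, function(s) {
    scene <- make_scene("white", seed = s, lead_in_s = 0.5)
    duo <- form_channels(scene$mic1, scene$mic2, default_geom)
    F1 <- stft(duo$ch1)
    lab <- classify_frames(F1, cepstral_tracker(), 10)
    ft <- F1$frame_times * 44100
    m <- scene$segment_marks
    lead <- ft + 1024 <= m["speech_start"]
    spch <- ft >= m["speech_start"] & ft + 1024 <= m["speech_end"]
    c(mean(lab$noise_only[lead]), mean(!lab$noise_only[spch]))
  }, numeric(2))
  expect_true(all(fracs[1, ] >= 0.8))   # lead-in labeled noise
  expect_true(all(fracs[2, ] >= 0.6))   # speech interval detected
})

test_that("pure stationary noise is labeled almost entirely noise-only", {
  fracs <- vapply(1:3, function(s) {
    ff <- noise_only_frames(90, kind = "white", seed = s)
    mean(classify_frames(ff$F1, cepstral_tracker(), 10)$noise_only)
  }, numeric(1))
  expect_gte(mean(fracs), 0.95)
})

test_that("classification requires more frames than the initialization window", {
  ff <- noise_only_frames(90, kind = "white", seed = 1, duration_s = 0.5)
  expect_error(classify_frames(ff$F1, cepstral_tracker(),
                               n_init = ncol(ff$F1$power)),
               "fewer frames")
})
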