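# Synthetic two-microphone scene simulator. Generates seeded acoustic scenes
# with the structure the enhancement algorithm assumes: a front speech source,
# one directional (possibly moving) interferer, far-field plane-wave
# propagation rendered as pure inter-microphone fractional delays, and a
# noise-only lead-in ahead of the speech.

#' Source specification
#'
#' Direction and level of an acoustic point source. Azimuth follows the array
#' convention: 0 degrees is the front (the desired-speech direction), angles
#' increase toward the side where 90 degrees is broadside-lateral; the
#' geometry is mirror-symmetric about the array axis.
#'
#' @param azimuth_deg Static azimuth in degrees, in `[0, 360)`.
#' @param trajectory Optional data.frame with columns `time_s` and
#'   `azimuth_deg` describing a piecewise-linear azimuth-vs-time path for a
#'   moving source. When given, `azimuth_deg` is the starting point.
#' @param rms_level Linear amplitude scale (default 1).
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(azimuth_deg = 0, trajectory = NULL, rms_level = 1) {
  if (azimuth_deg < 0 || azimuth_deg >= 360) stop("azimuth must lie in [0, 360)")
  if (rms_level < 0) stop("rms_level must be >= 0")
  if (!is.null(trajectory)) {
    if (!all(c("time_s", "azimuth_deg") %in% names(trajectory))) {
      stop("trajectory needs columns time_s and azimuth_deg")
    }
    if (any(trajectory$azimuth_deg < 0 | trajectory$azimuth_deg >= 360)) {
      stop("trajectory azimuths must lie in [0, 360)")
    }
  }
  structure(list(azimuth_deg = azimuth_deg, trajectory = trajectory,
                 rms_level = rms_level), class = "source_spec")
}

#' Generate a deterministic speech-like test signal
#'
#' An amplitude-modulated harmonic complex emulating voiced speech: harmonics
#' of `f0_hz` up to 5.5 kHz with a 1/h spectral roll-off, small jitter on the
#' fundamental, and a syllabic-rate (2-8 Hz) envelope with brief inter-word
#' gaps. Peak-normalized to at most 1 and fully determined by `seed`.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param f0_hz Fundamental frequency in Hz, 50-400.
#' @param seed Integer seed.
#' @param fs Sample rate in Hz.
#' @return An `audio` object.
#' @export
synth_speech_like <- function(duration_s, f0_hz = 120, seed = 1, fs = 44100) {
  if (!is.numeric(duration_s) || duration_s <= 0) stop("duration must be > 0")
  if (f0_hz < 50 || f0_hz > 400) stop("f0 must lie in [50, 400] Hz")
  n <- round(duration_s * fs)
  with_seed(seed, {
    t <- (0:(n - 1)) / fs
    # slow random f0 drift (a few percent) for naturalness
    drift <- stats::approx(seq(0, duration_s, length.out = 8),
                           stats::runif(8, -0.03, 0.03),
                           xout = t, rule = 2)$y
    phase0 <- cumsum(2 * pi * f0_hz * (1 + drift) / fs)
    nh <- max(1L, floor(5500 / f0_hz))
    x <- numeric(n)
    for (h in seq_len(nh)) {
      x <- x + sin(h * phase0 + stats::runif(1, 0, 2 * pi)) / h
    }
    # syllabic envelope: raised-cosine syllables at 2-8 Hz with word gaps
    env <- syllabic_envelope(n, fs)
    x <- x * env
    audio(x / max(abs(x)), fs)
  })
}

# raised-cosine syllable train with occasional gaps; deterministic under the
# caller's seed context
syllabic_envelope <- function(n, fs) {
  env <- numeric(n)
  pos <- 1L
  while (pos < n) {
    syl_rate <- stats::runif(1, 2, 8)            # syllables per second
    syl_len <- round(fs / syl_rate)
    idx <- pos:min(n, pos + syl_len - 1L)
    k <- seq_along(idx) - 1L
    amp <- stats::runif(1, 0.5, 1)
    env[idx] <- amp * 0.5 * (1 - cos(2 * pi * k / max(1L, syl_len - 1L)))
    pos <- pos + syl_len
    if (stats::runif(1) < 0.15) {                # inter-word gap 80-200 ms
      pos <- pos + round(stats::runif(1, 0.08, 0.2) * fs)
    }
  }
  env + 1e-3  # tiny pedestal so voicing never fully vanishes mid-syllable
}

#' Generate a deterministic noise test signal
#'
#' Three interferer families: `babble` (a sum of 5 independent speech-like
#' talkers, itself non-stationary and speech-shaped), `tonal_music` (a slowly
#' changing chord of sinusoids with note onsets and rests, strongly
#' non-stationary), and `white` (flat-spectrum Gaussian noise). All are
#' peak-normalized to at most 1 and fully determined by `seed`.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param kind One of `"babble"`, `"tonal_music"`, `"white"`.
#' @param seed Integer seed.
#' @param fs Sample rate in Hz.
#' @return An `audio` object.
#' @export
synth_noise <- function(duration_s, kind = c("babble", "tonal_music", "white"),
                        seed = 1, fs = 44100) {
  if (!is.numeric(duration_s) || duration_s <= 0) stop("duration must be > 0")
  kind <- match.arg(kind)
  n <- round(duration_s * fs)
  x <- switch(kind,
    white = with_seed(seed, stats::rnorm(n)),
    babble = {
      talkers <- 5L
      acc <- numeric(n)
      for (i in seq_len(talkers)) {
        f0 <- 90 + ((seed * 13 + i * 37) %% 160)  # spread of fundamentals
        acc <- acc + synth_speech_like(duration_s, f0, seed * 101 + i, fs)$samples
      }
      acc
    },
    tonal_music = with_seed(seed, tonal_music_samples(n, fs)))
  audio(x / max(abs(x)), fs)
}

tonal_music_samples <- function(n, fs) {
  # minor-pentatonic note pool, chords of 3-5 notes changing every 0.3-0.6 s,
  # raised-cosine onsets and occasional rests -> short-time energy swings well
  # beyond 6 dB
  pool <- 220 * 2^(c(0, 3, 5, 7, 10, 12, 15, 17, 19, 22, 24) / 12)
  x <- numeric(n)
  pos <- 1L
  while (pos < n) {
    seg <- round(stats::runif(1, 0.3, 0.6) * fs)
    idx <- pos:min(n, pos + seg - 1L)
    if (stats::runif(1) < 0.2) { pos <- pos + seg; next }  # rest
    notes <- sample(pool, sample(3:5, 1))
    amp <- stats::runif(1, 0.25, 1)
    t <- (idx - idx[1]) / fs
    ramp <- pmin(1, t / 0.03) * pmin(1, rev(t + 1 / fs) / 0.05)
    seg_x <- numeric(length(idx))
    for (f in notes) seg_x <- seg_x + sin(2 * pi * f * (idx - 1) / fs +
                                          stats::runif(1, 0, 2 * pi))
    x[idx] <- x[idx] + amp * ramp * seg_x
    pos <- pos + seg
  }
  x
}

#' Render a source at both microphones via its azimuth delay
#'
#' Far-field plane-wave rendering: microphone 1 receives the source as-is,
#' microphone 2 receives it delayed by (d/c) cos(azimuth) seconds (advanced
#' when the cosine is negative). The delay is realized with a high-accuracy
#' windowed-sinc interpolator (order 64), the simulator-side oracle against
#' which the 5-tap runtime filter is tested.
#'
#' @param src An `audio` object.
#' @param azimuth_deg Source azimuth in degrees.
#' @param geom An `array_geometry`.
#' @return A list with `audio` elements `at_mic1`, `at_mic2`.
#' @export
apply_azimuth_delay <- function(src, azimuth_deg, geom = array_geometry()) {
  stopifnot(inherits(src, "audio"), inherits(geom, "array_geometry"))
  if (length(src) == 0L) stop("source waveform is empty")
  D <- delay_samples(geom) * cos(azimuth_deg * pi / 180)
  list(at_mic1 = src, at_mic2 = audio(sinc_delay(src$samples, D), src$fs))
}

# Windowed-sinc fractional delay (Hann window, half-width 32 taps): y(n) =
# x(n - D). Handles negative D (advance). Zero padding at the edges.
sinc_delay <- function(x, D, half = 32L) {
  Di <- round(D)
  Df <- D - Di
  n <- length(x)
  y <- numeric(n)
  k <- (-half):half
  w <- 0.5 * (1 + cos(pi * k / (half + 1)))
  h <- sinc(k - Df) * w
  h <- h / sum(h)  # unity DC gain
  for (j in seq_along(k)) {
    s <- Di + k[j]          # y[n] += h_j * x[n - s]
    if (abs(h[j]) < 1e-12) next
    src_lo <- max(1L, 1L - s); src_hi <- min(n, n - s)
    if (src_lo > src_hi) next
    y[(src_lo + s):(src_hi + s)] <- y[(src_lo + s):(src_hi + s)] +
      h[j] * x[src_lo:src_hi]
  }
  y
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Block-wise moving-source delay: per-block constant azimuth (blocks <= 10 ms)
# read from the full source, so block joins stay continuous.
sinc_delay_moving <- function(x, delays_per_block, block_len) {
  n <- length(x)
  y <- numeric(n)
  for (b in seq_along(delays_per_block)) {
    lo <- (b - 1L) * block_len + 1L
    if (lo > n) break
    hi <- min(n, b * block_len)
    yb <- sinc_delay_segment(x, lo, hi, delays_per_block[b])
    y[lo:hi] <- yb
  }
  y
}

# delayed samples y[lo:hi] = x[(lo:hi) - D], reading from the whole x
sinc_delay_segment <- function(x, lo, hi, D, half = 32L) {
  Di <- round(D); Df <- D - Di
  k <- (-half):half
  w <- 0.5 * (1 + cos(pi * k / (half + 1)))
  h <- sinc(k - Df) * w
  h <- h / sum(h)
  n <- length(x)
  out <- numeric(hi - lo + 1L)
  for (j in seq_along(k)) {
    if (abs(h[j]) < 1e-12) next
    idx <- (lo:hi) - Di - k[j]
    ok <- idx >= 1L & idx <= n
    if (!any(ok)) next
    out[ok] <- out[ok] + h[j] * x[idx[ok]]
  }
  out
}

#' Simulate a two-microphone acoustic scene
#'
#' Builds a session of `lead_in_s` of noise alone, then the speech mixed with
#' noise, then `tail_s` of noise alone. The noise is scaled so the
#' speech-active region at microphone 1 has the requested input SNR
#' (10 log10 of speech power over noise power). Moving interferers are
#' rendered block-wise (10 ms blocks) along their trajectory. Both
#' microphones' speech and noise components are stored as clean references
#' for evaluation.
#'
#' @param speech An `audio` object (the desired source).
#' @param speech_src A `source_spec` for the speech (azimuth near 0).
#' @param noise An `audio` object at least as long as lead_in + speech + tail.
#' @param noise_src A `source_spec` for the interferer.
#' @param geom An `array_geometry`.
#' @param snr_db Input SNR in dB over the speech-active region at mic 1.
#' @param lead_in_s Noise-only lead-in duration in seconds (>= 0). The
#'   directivity estimator needs roughly 0.45 s or more to initialize well.
#' @param tail_s Noise-only tail duration in seconds.
#' @return An object of class `scene_session` with microphone signals
#'   (`mic1`, `mic2`), per-microphone clean components (`speech_mic1`,
#'   `speech_mic2`, `noise_mic1`, `noise_mic2`), `segment_marks` (sample
#'   indices: `speech_start`, `speech_end`), the geometry and the sources.
#' @export
simulate_scene <- function(speech, speech_src, noise, noise_src,
                           geom = array_geometry(), snr_db = 0,
                           lead_in_s = 3, tail_s = 1) {
  stopifnot(inherits(speech, "audio"), inherits(noise, "audio"),
            inherits(speech_src, "source_spec"),
            inherits(noise_src, "source_spec"),
            inherits(geom, "array_geometry"))
  if (lead_in_s < 0 || tail_s < 0) stop("lead_in and tail must be >= 0")
  fs <- geom$sample_rate_hz
  if (speech$fs != fs || noise$fs != fs) stop("sample rates must match the geometry")
  n_lead <- round(lead_in_s * fs)
  n_sp <- length(speech)
  n_tail <- round(tail_s * fs)
  n <- n_lead + n_sp + n_tail
  if (length(noise) < n) stop("noise must cover the whole session (lead_in + speech + tail)")

  sp1 <- numeric(n)
  sp1[(n_lead + 1L):(n_lead + n_sp)] <- speech$samples * speech_src$rms_level
  pair_sp <- apply_azimuth_delay(audio(sp1, fs), speech_src$azimuth_deg, geom)

  nz <- noise$samples[seq_len(n)] * noise_src$rms_level
  if (is.null(noise_src$trajectory)) {
    pair_nz <- apply_azimuth_delay(audio(nz, fs), noise_src$azimuth_deg, geom)
    nz1 <- pair_nz$at_mic1$samples
    nz2 <- pair_nz$at_mic2$samples
  } else {
    block <- round(0.010 * fs)
    nb <- ceiling(n / block)
    t_blk <- ((seq_len(nb) - 0.5) * block) / fs
    az <- stats::approx(noise_src$trajectory$time_s,
                        noise_src$trajectory$azimuth_deg,
                        xout = t_blk, rule = 2)$y
    delays <- delay_samples(geom) * cos(az * pi / 180)
    nz1 <- nz
    nz2 <- sinc_delay_moving(nz, delays, block)
  }

  # scale noise for the requested SNR over the speech-active region at mic 1
  sp_region <- (n_lead + 1L):(n_lead + n_sp)
  p_s <- sum(pair_sp$at_mic1$samples[sp_region]^2)
  p_n <- sum(nz1[sp_region]^2)
  if (p_n == 0) stop("noise has zero energy in the speech region")
  g <- sqrt(p_s / (p_n * 10^(snr_db / 10)))
  nz1 <- nz1 * g
  nz2 <- nz2 * g

  structure(list(
    mic1 = audio(pair_sp$at_mic1$samples + nz1, fs),
    mic2 = audio(pair_sp$at_mic2$samples + nz2, fs),
    speech_mic1 = pair_sp$at_mic1,
    speech_mic2 = pair_sp$at_mic2,
    noise_mic1 = audio(nz1, fs),
    noise_mic2 = audio(nz2, fs),
    segment_marks = c(speech_start = n_lead, speech_end = n_lead + n_sp),
    snr_db = snr_db,
    geom = geom,
    speech_src = speech_src,
    noise_src = noise_src
  ), class = "scene_session")
}

#' @export
print.scene_session <- function(x, ...) {
  cat(sprintf(
    "<scene_session> %.2f s @ %g Hz | speech az %g deg, noise az %g deg%s | SNR %g dB\n",
    duration(x$mic1), x$mic1$fs, x$speech_src$azimuth_deg,
    x$noise_src$azimuth_deg,
    if (is.null(x$noise_src$trajectory)) "" else " (moving)",
    x$snr_db))
  cat(sprintf(" speech span: samples %d-%d (lead-in %.3f s)\n",
              x$segment_marks[1] + 1L, x$segment_marks[2],
              x$segment_marks[1] / x$mic1$fs))
  invisible(x)
}
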