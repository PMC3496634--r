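# shared fixtures built in code

default_geom <- array_geometry()

# a small 0 dB scene: lead-in of noise, speech from the front area, tail
make_scene <- function(noise_kind = "babble", speech_az = 0, noise_az = 90,
                       seed = 1, lead_in_s = 0.5, speech_s = 1.2,
                       tail_s = 0.3, snr_db = 0, trajectory = NULL) {
  sp <- synth_speech_like(speech_s, 120, seed = seed)
  nz <- synth_noise(lead_in_s + speech_s + tail_s + 0.1, noise_kind,
                    seed = seed + 1000L)
  simulate_scene(sp, source_spec(speech_az), nz,
                 source_spec(noise_az, trajectory), default_geom,
                 snr_db = snr_db, lead_in_s = lead_in_s, tail_s = tail_s)
}

# noise-only session rendered at a given azimuth, as dual channels + frames
noise_only_frames <- function(azimuth_deg, kind = "tonal_music", seed = 11,
                              duration_s = 2) {
  nz <- synth_noise(duration_s, kind, seed = seed)
  pr <- apply_azimuth_delay(nz, azimuth_deg, default_geom)
  duo <- form_channels(pr$at_mic1, pr$at_mic2, default_geom)
  list(F1 = stft(duo$ch1), F2 = stft(duo$ch2))
}

cot4 <- function(phi_deg) (cos(phi_deg * pi / 360) / sin(phi_deg * pi / 360))^4

# delay between two waveforms by parabolic-interpolated cross-correlation;
# both are band-limited to the filter's accuracy band first so the
# correlation peak is smooth enough for the parabola fit
xcorr_delay <- function(x, y, max_lag = 8, fs = 44100) {
  flt <- signal::butter(4, c(100, 6000) / (fs / 2), type = "pass")
  x <- signal::filtfilt(flt, x)
  y <- signal::filtfilt(flt, y)
  xcorr_delay_raw(x, y, max_lag)
}

xcorr_delay_raw <- function(x, y, max_lag = 8) {
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(x[1:(length(x) - l)] * y[(1 + l):length(y)])
    else sum(x[(1 - l):length(x)] * y[1:(length(y) + l)])
  }, numeric(1))
  i <- which.max(cc)
  if (i == 1 || i == length(cc)) return(lags[i])
  num <- cc[i - 1] - cc[i + 1]
  den <- 2 * (cc[i - 1] - 2 * cc[i] + cc[i + 1])
  lags[i] + num / den
}

band_rms <- function(x, fs = 44100, lo = 100, hi = 6000) {
  flt <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  sqrt(mean(signal::filtfilt(flt, x)^2))
}
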