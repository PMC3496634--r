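# CIS sine-simulation stage: 16-band analysis, envelope extraction, and
# sine-carrier synthesis at the band centers. This is the acoustic model of
# the implant's continuous-interleaved-sampling processing under which
# spectral detail inside each band collapses onto the band's carrier --
# the stage that shrinks the apparent distortion of aggressive enhancement.

#' Vocoder configuration
#'
#' @param band_table A `band_table` (default: the 16-band CI table).
#' @param envelope_cutoff_hz Envelope low-pass cutoff in Hz (default 400,
#'   standard CIS practice).
#' @param filter_order Band-pass filter order (default 4; must be an even
#'   number >= 2).
#' @return An object of class `vocoder_config`.
#' @export
vocoder_config <- function(band_table = build_default_band_table(),
                           envelope_cutoff_hz = 400, filter_order = 4) {
  validate_band_table(band_table)
  if (filter_order < 2 || filter_order %% 2 != 0) {
    stop("filter_order must be an even integer >= 2")
  }
  if (envelope_cutoff_hz <= 0) stop("envelope cutoff must be positive")
  structure(list(band_table = band_table,
                 envelope_cutoff_hz = envelope_cutoff_hz,
                 filter_order = as.integer(filter_order)),
            class = "vocoder_config")
}

#' Split a signal into the CI analysis bands
#'
#' Zero-phase (forward-backward) Butterworth band-pass filtering through each
#' band of the table, so all bands stay time-aligned.
#'
#' @param x An `audio` object; sample rate must be at least twice the top
#'   band edge.
#' @param cfg A `vocoder_config`.
#' @return A matrix with one column per band (samples x bands).
#' @export
analyze_bands <- function(x, cfg = vocoder_config()) {
  stopifnot(inherits(x, "audio"), inherits(cfg, "vocoder_config"))
  tab <- cfg$band_table
  if (x$fs < 2 * max(tab$hi_hz)) stop("sample rate too low for the band table")
  out <- matrix(0, length(x), nrow(tab))
  for (j in seq_len(nrow(tab))) {
    flt <- signal::butter(cfg$filter_order / 2,
                          c(tab$lo_hz[j], tab$hi_hz[j]) / (x$fs / 2),
                          type = "pass")
    out[, j] <- signal::filtfilt(flt, x$samples)
  }
  out
}

#' Extract the envelope of a band signal
#'
#' Full-wave rectification followed by a 2nd-order zero-phase low-pass at the
#' configured cutoff; clamped to be non-negative.
#'
#' @param band Numeric vector (one band-limited waveform).
#' @param cfg A `vocoder_config`.
#' @param fs Sample rate in Hz.
#' @return Non-negative envelope waveform.
#' @export
extract_envelope <- function(band, cfg = vocoder_config(), fs = 44100) {
  flt <- signal::butter(2, cfg$envelope_cutoff_hz / (fs / 2), type = "low")
  pmax(0, signal::filtfilt(flt, abs(band)))
}

#' CIS sine vocoder
#'
#' Band-splits the input, extracts each band's envelope, modulates a
#' sinusoidal carrier at the band's center frequency, and sums:
#' \deqn{y(t) = \sum_b env_b(t) \sin(2\pi f_b t).}
#' The output is peak-normalized to the input peak. No amplitude compression
#' or loudness mapping is applied (identity compression; `compression_map`
#' is a hook for future maps).
#'
#' @param x An `audio` object.
#' @param cfg A `vocoder_config`.
#' @param compression_map Optional function applied to each envelope.
#' @return An `audio` object.
#' @export
vocode <- function(x, cfg = vocoder_config(), compression_map = identity) {
  stopifnot(inherits(x, "audio"))
  bands <- analyze_bands(x, cfg)
  t <- (seq_len(length(x)) - 1L) / x$fs
  y <- numeric(length(x))
  for (j in seq_len(ncol(bands))) {
    env <- compression_map(extract_envelope(bands[, j], cfg, x$fs))
    y <- y + env * sin(2 * pi * cfg$band_table$center_hz[j] * t)
  }
  pk_in <- max(abs(x$samples))
  pk_out <- max(abs(y))
  if (pk_out > 0 && pk_in > 0) y <- y * (pk_in / pk_out)
  audio(y, x$fs)
}
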