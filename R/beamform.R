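# First-order differential beamformer: forms the two channels whose nulls
# separate front speech from directional noise. Channel 1 nulls the rear
# (180 deg), channel 2 nulls the front (0 deg), so channel 2 carries
# essentially no desired speech while both carry the directional noise with
# azimuth-dependent gains.

#' Form the two differential channels from a microphone pair
#'
#' Cross-delayed differences of the two microphone signals:
#' \deqn{ch_1(t) = MIC_1(t) - MIC_2(t - d/c), \qquad
#'       ch_2(t) = MIC_2(t) - MIC_1(t - d/c),}
#' where the d/c delay is realized by the supplied maximally-flat
#' fractional-delay filter. For a front source ch2 vanishes (front null); for
#' a rear source ch1 vanishes (rear null).
#'
#' @param mic1,mic2 `audio` objects (the two time-aligned microphones), equal
#'   length and sample rate.
#' @param geom An `array_geometry`.
#' @param filt A `delay_filter` whose nominal delay matches the geometry's
#'   d/c within 0.01 samples. Defaults to the order-4 maximally-flat design
#'   at the geometry delay.
#' @return An object of class `dual_channels` with `audio` fields `ch1`,
#'   `ch2`, plus the geometry and filter used.
#' @export
form_channels <- function(mic1, mic2, geom = array_geometry(),
                          filt = design_maxflat_delay(delay_samples(geom), 4)) {
  stopifnot(inherits(mic1, "audio"), inherits(mic2, "audio"),
            inherits(geom, "array_geometry"), inherits(filt, "delay_filter"))
  if (length(mic1) != length(mic2)) stop("microphone channels must have equal length")
  if (mic1$fs != mic2$fs) stop("microphone channels must share a sample rate")
  if (abs(filt$nominal_delay_samples - delay_samples(geom)) > 0.01) {
    stop("delay filter's nominal delay does not match the geometry's d/c")
  }
  ch1 <- mic1$samples - apply_delay(mic2$samples, filt)
  ch2 <- mic2$samples - apply_delay(mic1$samples, filt)
  structure(list(ch1 = audio(ch1, mic1$fs), ch2 = audio(ch2, mic2$fs),
                 geom = geom, delay_filter = filt),
            class = "dual_channels")
}

#' @export
print.dual_channels <- function(x, ...) {
  cat(sprintf("<dual_channels> %d samples @ %g Hz (differential pair)\n",
              length(x$ch1), x$ch1$fs))
  invisible(x)
}

# Closed-form per-bin power ratio |CH1|^2/|CH2|^2 for a point source at
# azimuth phi: sin^2(0.5 w d/c (1+cos phi)) / sin^2(0.5 w d/c (1-cos phi)).
# Used in tests and as the scalar cold-start model.
channel_power_ratio_theory <- function(f_hz, phi_deg, geom = array_geometry()) {
  wdc <- 2 * pi * f_hz * delay_seconds(geom)
  cphi <- cos(phi_deg * pi / 180)
  (sin(0.5 * wdc * (1 + cphi)))^2 / (sin(0.5 * wdc * (1 - cphi)))^2
}
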