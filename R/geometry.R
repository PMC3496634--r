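#' Microphone array geometry
#'
#' Describes the two-microphone end-to-end geometry: inter-microphone spacing
#' `d`, sound speed `c` and the sample rate. The derived inter-microphone
#' travel time d/c, expressed in samples, is the delay every stage of the
#' algorithm uses; with the defaults (d = 0.01 m, c = 340 m/s, fs = 44.1 kHz)
#' it equals 1.297 samples.
#'
#' @param mic_spacing_m Spacing between the two omnidirectional microphones in
#'   meters (default 0.01, the cochlear-implant size constraint).
#' @param sound_speed_mps Speed of sound in m/s (default 340).
#' @param sample_rate_hz Sample rate in Hz (default 44100).
#' @return An object of class `array_geometry`.
#' @examples
#' g <- array_geometry()
#' delay_samples(g)  # 1.297
#' @export
array_geometry <- function(mic_spacing_m = 0.01, sound_speed_mps = 340,
                           sample_rate_hz = 44100) {
  if (mic_spacing_m <= 0 || sound_speed_mps <= 0 || sample_rate_hz <= 0) {
    stop("all geometry fields must be strictly positive")
  }
  structure(list(mic_spacing_m = mic_spacing_m,
                 sound_speed_mps = sound_speed_mps,
                 sample_rate_hz = sample_rate_hz),
            class = "array_geometry")
}

#' Inter-microphone delay in samples
#'
#' @param geom An `array_geometry`.
#' @return The travel time d/c expressed in samples: d/c * fs.
#' @export
delay_samples <- function(geom) {
  stopifnot(inherits(geom, "array_geometry"))
  geom$mic_spacing_m / geom$sound_speed_mps * geom$sample_rate_hz
}

# d/c in seconds
delay_seconds <- function(geom) geom$mic_spacing_m / geom$sound_speed_mps

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("<array_geometry> d = %g m, c = %g m/s, fs = %g Hz (d/c = %.4f samples)\n",
              x$mic_spacing_m, x$sound_speed_mps, x$sample_rate_hz,
              delay_samples(x)))
  invisible(x)
}
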