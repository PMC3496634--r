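# Lightweight audio container: a numeric sample vector plus its sample rate.
# All processing stages exchange this class.

#' Create an audio signal
#'
#' Wraps a numeric waveform and its sample rate into an `audio` object, the
#' carrier used by every stage of the package (simulation, beamforming,
#' enhancement, vocoding, metrics).
#'
#' @param samples Numeric vector of samples.
#' @param fs Sample rate in Hz (default 44100, the rate the algorithm is
#'   designed for).
#' @return An object of class `audio`.
#' @examples
#' a <- audio(sin(2 * pi * 440 * (0:999) / 44100))
#' duration(a)
#' @export
audio <- function(samples, fs = 44100) {
  if (!is.numeric(samples)) stop("'samples' must be numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a single positive number")
  }
  structure(list(samples = as.numeric(samples), fs = fs), class = "audio")
}

#' @export
print.audio <- function(x, ...) {
  cat(sprintf("<audio> %d samples @ %g Hz (%.3f s), peak %.4g\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' @export
length.audio <- function(x) length(x$samples)

#' Duration of an audio signal in seconds
#' @param x An `audio` object.
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio"))
  length(x$samples) / x$fs
}

# Coerce numeric vectors or audio objects to audio at a given rate.
as_audio <- function(x, fs = 44100) {
  if (inherits(x, "audio")) return(x)
  audio(x, fs)
}

#' Resample an audio signal
#'
#' Polyphase resampling (via \code{signal::resample}) used on ingest so all
#' internal processing runs at the design rate of 44.1 kHz.
#'
#' @param x An `audio` object.
#' @param fs_out Target sample rate in Hz.
#' @return An `audio` object at `fs_out`.
#' @export
resample_audio <- function(x, fs_out = 44100) {
  stopifnot(inherits(x, "audio"))
  if (x$fs == fs_out) return(x)
  r <- gcd_int(round(fs_out), round(x$fs))
  p <- round(fs_out) / r
  q <- round(x$fs) / r
  audio(signal::resample(x$samples, p, q), fs_out)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Evaluate a deterministic seeded expression without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}
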