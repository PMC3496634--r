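# Short-time analysis/synthesis: Hamming-windowed frames of 1024 samples with
# 50 % overlap, and the overlap-add inverse with summed-window normalization.

#' Short-time framing configuration
#'
#' @param frame_len Frame length in samples, a power of two (default 1024,
#'   about 23 ms at 44.1 kHz).
#' @param hop Hop size in samples; must equal `frame_len / 2` (50 % overlap).
#' @param window Window identifier; only `"hamming"` is supported.
#' @return An object of class `frame_config`.
#' @export
frame_config <- function(frame_len = 1024, hop = frame_len / 2,
                         window = "hamming") {
  if (frame_len < 2 || bitwAnd(frame_len, frame_len - 1L) != 0) {
    stop("frame_len must be a power of two")
  }
  if (hop != frame_len / 2) stop("hop must be frame_len/2 (50% overlap)")
  if (!identical(window, "hamming")) stop("only the Hamming window is supported")
  structure(list(frame_len = as.integer(frame_len), hop = as.integer(hop),
                 window = window), class = "frame_config")
}

window_vector <- function(cfg) {
  n <- cfg$frame_len
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Short-time Fourier transform
#'
#' Windows the signal into half-overlapping Hamming frames and transforms
#' each; keeps the non-negative-frequency bins (frame_len/2 + 1 of them).
#'
#' @param x An `audio` object, at least one frame long.
#' @param cfg A `frame_config`.
#' @return An object of class `spectral_frames` with complex matrix `spec`
#'   (bins x frames), `power` (squared magnitudes), `freqs` (Hz per bin),
#'   `frame_times` (seconds, frame starts), `fs`, `cfg`, and the original
#'   signal length `n_orig`.
#' @export
stft <- function(x, cfg = frame_config()) {
  stopifnot(inherits(x, "audio"), inherits(cfg, "frame_config"))
  n <- length(x)
  if (n < cfg$frame_len) stop("signal shorter than one frame")
  nf <- (n - cfg$frame_len) %/% cfg$hop + 1L
  starts <- (seq_len(nf) - 1L) * cfg$hop
  w <- window_vector(cfg)
  m <- matrix(0, cfg$frame_len, nf)
  for (j in seq_len(nf)) {
    m[, j] <- x$samples[(starts[j] + 1L):(starts[j] + cfg$frame_len)] * w
  }
  Z <- stats::mvfft(m)
  nb <- cfg$frame_len %/% 2L + 1L
  spec <- Z[seq_len(nb), , drop = FALSE]
  structure(list(spec = spec,
                 power = Mod(spec)^2,
                 freqs = (seq_len(nb) - 1L) * x$fs / cfg$frame_len,
                 frame_times = starts / x$fs,
                 fs = x$fs, cfg = cfg, n_orig = n),
            class = "spectral_frames")
}

#' @export
print.spectral_frames <- function(x, ...) {
  cat(sprintf("<spectral_frames> %d bins x %d frames @ %g Hz (frame %d, hop %d)\n",
              nrow(x$spec), ncol(x$spec), x$fs, x$cfg$frame_len, x$cfg$hop))
  invisible(x)
}

# rebuild the full conjugate-symmetric spectrum from the stored half
full_spectrum <- function(half, frame_len) {
  nb <- nrow(half)
  rbind(half, Conj(half[(nb - 1L):2L, , drop = FALSE]))
}

#' Inverse STFT by overlap-add
#'
#' Inverse-transforms each frame, overlap-adds at the hop, and divides by the
#' overlap-added analysis window (synthesis window rectangular) so that
#' `istft_overlap_add(stft(x))` reproduces `x` on the fully-overlapped
#' interior to numerical precision.
#'
#' @param frames A `spectral_frames` object (its `spec` field is used; it may
#'   have been modified, e.g. by the enhancement gain mask).
#' @return An `audio` object of the original analyzed length.
#' @export
istft_overlap_add <- function(frames) {
  stopifnot(inherits(frames, "spectral_frames"))
  cfg <- frames$cfg
  nf <- ncol(frames$spec)
  full <- full_spectrum(frames$spec, cfg$frame_len)
  td <- Re(stats::mvfft(full, inverse = TRUE)) / cfg$frame_len
  n <- frames$n_orig
  y <- numeric(n)
  wsum <- numeric(n)
  w <- window_vector(cfg)
  starts <- (seq_len(nf) - 1L) * cfg$hop
  for (j in seq_len(nf)) {
    idx <- (starts[j] + 1L):(starts[j] + cfg$frame_len)
    y[idx] <- y[idx] + td[, j]
    wsum[idx] <- wsum[idx] + w
  }
  audio(y / pmax(wsum, 1e-12), frames$fs)
}
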