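# Maximally-flat FIR fractional-delay filter (equivalently, Lagrange
# interpolation). This is the runtime d/c delay used when forming the two
# differential channels.

#' Design a maximally-flat FIR fractional-delay filter
#'
#' Designs an order-`order` FIR filter approximating a pure delay of
#' `delay_samples` samples with a maximally-flat frequency-response error at
#' DC. For this order/delay regime the maximally-flat design coincides with
#' Lagrange interpolation, so the taps are computed in closed form:
#' \deqn{h(n) = \prod_{k \ne n} \frac{D - k}{n - k}, \qquad n = 0,\dots,N.}
#' With the default geometry delay D = 1.297 samples and N = 4 this gives the
#' 5-tap filter (-0.0400, 0.6995, 0.4433, -0.1220, 0.0192).
#'
#' @param delay_samples Desired delay D in samples, in `[0, order]`.
#' @param order Filter order N (number of taps minus one), at least 1.
#' @return An object of class `delay_filter` with fields `taps`,
#'   `nominal_delay_samples`, `order`.
#' @examples
#' design_maxflat_delay(1.297, 4)$taps
#' @export
design_maxflat_delay <- function(delay_samples, order = 4) {
  if (order < 1 || order != round(order)) stop("'order' must be an integer >= 1")
  if (delay_samples < 0 || delay_samples > order) {
    stop("'delay_samples' must lie in [0, order]; the design is ill-conditioned outside")
  }
  k <- 0:order
  taps <- vapply(k, function(n) {
    others <- k[k != n]
    prod((delay_samples - others) / (n - others))
  }, numeric(1))
  structure(list(taps = taps,
                 nominal_delay_samples = delay_samples,
                 order = as.integer(order)),
            class = "delay_filter")
}

#' @export
print.delay_filter <- function(x, ...) {
  cat(sprintf("<delay_filter> order %d, nominal delay %.4f samples\n taps: %s\n",
              x$order, x$nominal_delay_samples,
              paste(sprintf("% .4f", x$taps), collapse = " ")))
  invisible(x)
}

#' Apply a fractional-delay filter to a signal
#'
#' Causal convolution with the filter taps, truncated to the input length.
#' The first `order` output samples are transient; sessions carry a noise
#' lead-in long enough that the transient never overlaps speech.
#'
#' @param x An `audio` object or numeric vector.
#' @param filt A `delay_filter`.
#' @return Delayed signal, same class and length as the input.
#' @export
apply_delay <- function(x, filt) {
  stopifnot(inherits(filt, "delay_filter"))
  samples <- if (inherits(x, "audio")) x$samples else x
  n <- length(samples)
  y <- stats::filter(samples, filt$taps, method = "convolution",
                     sides = 1)
  y <- as.numeric(y)
  # stats::filter(sides = 1) leaves leading NAs for the transient
  y[is.na(y)] <- cumsum_head_conv(samples, filt$taps)[is.na(y)]
  if (inherits(x, "audio")) audio(y, x$fs) else y
}

# explicit head of the convolution for the first length(taps)-1 samples
cumsum_head_conv <- function(x, h) {
  m <- length(h) - 1L
  head <- numeric(min(m, length(x)))
  for (n in seq_along(head)) {
    k <- 0:(n - 1L)
    head[n] <- sum(h[k + 1L] * x[n - k])
  }
  c(head, numeric(length(x) - length(head)))
}

#' Frequency-response error of a fractional-delay filter
#'
#' Evaluates the filter's deviation from the ideal all-pass delay
#' \eqn{e^{-j\omega D}} on a uniform frequency grid. The magnitude error is
#' \eqn{\max | |H| - 1 |}; the phase error is the maximum of
#' \eqn{|(\arg H + \omega D) / (\omega D)|} excluding DC, i.e. relative to the
#' ideal linear phase. Both are returned as fractions (0.003 = 0.3 %).
#'
#' @param filt A `delay_filter`.
#' @param f_lo_hz,f_hi_hz Band edges in Hz, `0 <= f_lo < f_hi <= fs/2`.
#' @param fs_hz Sample rate in Hz.
#' @param n_grid Number of grid frequencies (default 2048).
#' @return Named numeric vector `c(max_mag_err, max_phase_err)`, as fractions.
#' @examples
#' response_error(design_maxflat_delay(1.297, 4), 0, 6000, 44100)
#' @export
response_error <- function(filt, f_lo_hz = 0, f_hi_hz = 6000, fs_hz = 44100,
                           n_grid = 2048) {
  stopifnot(inherits(filt, "delay_filter"))
  if (f_lo_hz < 0 || f_hi_hz <= f_lo_hz || f_hi_hz > fs_hz / 2) {
    stop("require 0 <= f_lo < f_hi <= fs/2")
  }
  f <- seq(f_lo_hz, f_hi_hz, length.out = n_grid)
  w <- 2 * pi * f / fs_hz
  n <- 0:filt$order
  H <- vapply(w, function(om) sum(filt$taps * exp(-1i * om * n)), complex(1))
  mag_err <- max(abs(Mod(H) - 1))
  D <- filt$nominal_delay_samples
  nz <- w > 0
  phase_err <- if (D == 0 || !any(nz)) 0 else
    max(abs((Arg(H[nz]) + w[nz] * D) / (w[nz] * D)))
  c(max_mag_err = mag_err, max_phase_err = phase_err)
}

#' Export filter taps as JSON
#'
#' @param filt A `delay_filter`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_delay_filter_json <- function(filt, path) {
  stopifnot(inherits(filt, "delay_filter"))
  jsonlite::write_json(list(order = filt$order,
                            nominal_delay_samples = filt$nominal_delay_samples,
                            taps = filt$taps),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
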