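# Broadband gain compensation for the differential array's low-frequency
# roll-off. The magnitude estimator's numerator carries the array factor
# 2 sin(2 pi f d/c); the compensating gain lambda(f) = 1 / (2 sin(2 pi f d/c))
# restores a flat speech response. It is applied either per CI filter-bank
# band (the 16-band table of adjusting coefficients) or through a first-order
# Butterworth band-pass approximation with a 30x post-gain.

#' Low-frequency compensation gain lambda(f)
#'
#' \deqn{\lambda(f) = \frac{1}{2 \sin(2 \pi f d / c)}}
#' with d/c taken from the geometry. Monotone decreasing on 100-6000 Hz.
#'
#' @param f_hz Frequency (or vector of frequencies) in Hz, each in
#'   (0, fs/2) with a positive sine argument.
#' @param geom An `array_geometry`.
#' @return Linear gain(s).
#' @examples
#' lambda_gain(216)   # ~12.53, the channel-1 adjusting coefficient
#' @export
lambda_gain <- function(f_hz, geom = array_geometry()) {
  stopifnot(inherits(geom, "array_geometry"))
  if (any(f_hz <= 0 | f_hz >= geom$sample_rate_hz / 2)) {
    stop("f must lie in (0, fs/2)")
  }
  s <- sin(2 * pi * f_hz * delay_seconds(geom))
  if (any(s <= 0)) stop("sin(2 pi f d/c) must be positive at every f")
  1 / (2 * s)
}

# the 16-band CI filter-bank layout: band edges and centers in Hz
ci_band_edges <- c(156, 276, 410, 560, 730, 922, 1138, 1380, 1653, 1960,
                   2305, 2694, 3131, 3623, 4176, 4798, 5498)
ci_band_centers <- c(216, 343, 485, 645, 826, 1030, 1259, 1517, 1807, 2133,
                     2500, 2913, 3377, 3840, 4487, 5148)
# adjusting coefficients as printed in the source table; channels 10 and 14
# (1.2135, 0.7578) disagree with lambda evaluated at their centers (~1.302,
# ~0.767) and are reproduced only in verbatim mode
ci_coeff_verbatim <- c(12.5294, 7.8934, 5.5861, 4.2047, 3.2883, 2.6428,
                       2.1685, 1.8071, 1.5255, 1.2135, 1.1217, 0.9752,
                       0.8557, 0.7578, 0.6781, 0.6141)

#' Build the default 16-band CI band table
#'
#' The standard 16-band CI filter-bank layout spanning 156-5498 Hz, with each
#' band's adjusting coefficient computed as `lambda_gain` at its center
#' frequency. `verbatim = TRUE` instead reproduces the published coefficient
#' column unchanged; its channels 10 and 14 are inconsistent with the
#' lambda formula evaluated at their centers (apparently typographical) and
#' differ from the recomputed values by about 7 and 1 percent.
#'
#' @param geom An `array_geometry`.
#' @param verbatim If TRUE, use the published coefficients as printed.
#' @return An object of class `band_table`: a data.frame with columns
#'   `channel`, `lo_hz`, `hi_hz`, `center_hz`, `coeff`.
#' @export
build_default_band_table <- function(geom = array_geometry(),
                                     verbatim = FALSE) {
  coeff <- if (verbatim) ci_coeff_verbatim else lambda_gain(ci_band_centers, geom)
  tab <- data.frame(channel = seq_len(16),
                    lo_hz = ci_band_edges[-17],
                    hi_hz = ci_band_edges[-1],
                    center_hz = ci_band_centers,
                    coeff = coeff)
  class(tab) <- c("band_table", "data.frame")
  tab
}

validate_band_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("lo_hz", "hi_hz", "center_hz", "coeff") %in% names(tab)))
  if (any(tab$coeff <= 0)) stop("band coefficients must be positive")
  if (any(diff(tab$lo_hz) <= 0) || any(tab$hi_hz <= tab$lo_hz)) {
    stop("bands must be increasing")
  }
  invisible(tab)
}

#' Compensation filter specification
#'
#' Either direct per-band multiplication by the band table's adjusting
#' coefficients (`mode = "band_table"`, the filter-bank transfer path) or a
#' first-order Butterworth band-pass approximation of the scaled gain
#' lambda'(f) = lambda(f)/30 followed by a 30x post-gain
#' (`mode = "butterworth"`, for strategies without a filter bank).
#'
#' @param mode `"band_table"` or `"butterworth"`.
#' @param butter_low_hz,butter_high_hz Band-pass cutoffs in Hz.
#' @param post_gain_linear Post-gain (default 30, i.e. 29.54 dB).
#' @param fs_hz Sample rate in Hz.
#' @return An object of class `compensation_filter`.
#' @export
compensation_filter <- function(mode = c("band_table", "butterworth"),
                                butter_low_hz = 0.00045 * fs_hz,
                                butter_high_hz = 0.0045 * fs_hz,
                                post_gain_linear = 30, fs_hz = 44100) {
  mode <- match.arg(mode)
  if (post_gain_linear <= 0) stop("post_gain must be positive")
  if (butter_low_hz <= 0 || butter_high_hz >= fs_hz / 2 ||
      butter_high_hz <= butter_low_hz) {
    stop("cutoffs must satisfy 0 < low < high < fs/2")
  }
  structure(list(mode = mode, butter_low_hz = butter_low_hz,
                 butter_high_hz = butter_high_hz,
                 post_gain_linear = post_gain_linear, fs_hz = fs_hz),
            class = "compensation_filter")
}

#' Design the Butterworth approximation of the compensation gain
#'
#' First-order Butterworth band-pass with cutoffs 0.00045 fs and 0.0045 fs
#' (19.845 and 198.45 Hz at 44.1 kHz) whose magnitude response, times the
#' 30x (29.54 dB) post-gain, approximates lambda(f) over 100-6000 Hz.
#'
#' @param fs_hz Sample rate in Hz.
#' @param geom An `array_geometry` (carried for response comparisons).
#' @return A `compensation_filter` in butterworth mode.
#' @export
design_butterworth_approx <- function(fs_hz = 44100, geom = array_geometry()) {
  compensation_filter("butterworth", fs_hz = fs_hz)
}

# magnitude response of the compensation Butterworth (without post-gain)
butter_comp_response <- function(comp, f_hz) {
  flt <- signal::butter(1, c(comp$butter_low_hz, comp$butter_high_hz) /
                             (comp$fs_hz / 2), type = "pass")
  vapply(2 * pi * f_hz / comp$fs_hz, function(om) {
    z <- exp(-1i * om * (seq_along(flt$b) - 1))
    Mod(sum(flt$b * z) / sum(flt$a * z))
  }, numeric(1))
}

#' Post-gain of a compensation filter in dB
#' @param comp A `compensation_filter`.
#' @return Gain in dB (29.54 for the default 30x).
#' @export
post_gain_db <- function(comp) 20 * log10(comp$post_gain_linear)

#' Apply broadband compensation to per-bin magnitudes
#'
#' In `band_table` mode each bin is multiplied by its band's adjusting
#' coefficient; bins outside all bands take the nearest band's coefficient
#' (lambda itself diverges toward DC, so no extrapolation). In `butterworth`
#' mode each bin is multiplied by the band-pass magnitude response times the
#' post-gain.
#'
#' @param magnitudes Non-negative per-bin magnitudes.
#' @param freqs Bin frequencies in Hz, aligned with `magnitudes`.
#' @param comp A `compensation_filter`.
#' @param table A `band_table` (used in band_table mode).
#' @return Compensated magnitudes.
#' @export
apply_compensation <- function(magnitudes, freqs,
                               comp = compensation_filter(),
                               table = build_default_band_table()) {
  stopifnot(length(magnitudes) == length(freqs),
            inherits(comp, "compensation_filter"))
  magnitudes * compensation_gains(freqs, comp, table)
}

compensation_gains <- function(freqs, comp, table) {
  if (comp$mode == "band_table") {
    validate_band_table(table)
    g <- numeric(length(freqs))
    band_of <- findInterval(freqs, c(table$lo_hz, table$hi_hz[nrow(table)]),
                            rightmost.closed = TRUE)
    inside <- band_of >= 1 & band_of <= nrow(table)
    g[inside] <- table$coeff[band_of[inside]]
    g[freqs < table$lo_hz[1]] <- table$coeff[1]
    g[freqs >= table$hi_hz[nrow(table)]] <- table$coeff[nrow(table)]
    g
  } else {
    resp <- numeric(length(freqs))
    pos <- freqs > 0
    resp[pos] <- butter_comp_response(comp, freqs[pos])
    resp * comp$post_gain_linear
  }
}

#' Write a band table to JSON or CSV
#'
#' @param table A `band_table`.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return The path, invisibly.
#' @export
write_band_table <- function(table, path) {
  validate_band_table(table)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(table), path, digits = NA)
  } else {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a band table from JSON or CSV
#' @param path Input path (`.json` or `.csv`).
#' @return A `band_table`.
#' @export
read_band_table <- function(path) {
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)
  }
  class(tab) <- c("band_table", "data.frame")
  validate_band_table(tab)
  tab
}
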