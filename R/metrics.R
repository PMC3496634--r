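# Evaluation: input/output SNR, band-weighted Delta-SNR via shadow
# decomposition of the enhancement gain mask, and the speech distortion
# index.

#' Signal-to-noise ratio in dB
#'
#' `10 log10(sum(s^2) / sum(n^2))` over the full extent of the references.
#'
#' @param speech_ref,noise_ref `audio` objects or numeric vectors of equal
#'   length.
#' @return SNR in dB; `Inf` (with a warning) when the noise has zero energy.
#' @export
snr_db <- function(speech_ref, noise_ref) {
  s <- if (inherits(speech_ref, "audio")) speech_ref$samples else speech_ref
  n <- if (inherits(noise_ref, "audio")) noise_ref$samples else noise_ref
  if (length(s) != length(n)) stop("references must have equal length")
  pn <- sum(n^2)
  if (pn == 0) {
    warning("noise reference has zero energy: SNR is infinite")
    return(Inf)
  }
  10 * log10(sum(s^2) / pn)
}

#' Shadow-decompose an enhancement run into speech and noise components
#'
#' Applies the per-frame, per-bin gain mask the pipeline applied to the
#' mixture to the scene's clean speech-only and noise-only components
#' (rendered through the same differential front end and framing), yielding
#' the enhanced output's speech part s-hat and noise part n-hat. Because the
#' mask and the channel formation are linear, `s_hat + n_hat` equals the
#' enhanced output to numerical precision, so output SNR can be measured
#' without access to ground truth inside the pipeline.
#'
#' @param fit A `dcse_enhance` object (with `phase = "ch1"`, the default).
#' @param scene The `scene_session` the fit was run on (carries the
#'   per-microphone clean components).
#' @return A list with `audio` elements `s_hat`, `n_hat`.
#' @export
shadow_decompose <- function(fit, scene) {
  stopifnot(inherits(fit, "dcse_enhance"), inherits(scene, "scene_session"))
  if (is.null(scene$speech_mic1) || is.null(scene$noise_mic1)) {
    stop("scene does not carry clean references")
  }
  duo_s <- form_channels(scene$speech_mic1, scene$speech_mic2,
                         fit$geom, fit$delay_filter)
  duo_n <- form_channels(scene$noise_mic1, scene$noise_mic2,
                         fit$geom, fit$delay_filter)
  Fs <- stft(duo_s$ch1, fit$frame)
  Fn <- stft(duo_n$ch1, fit$frame)
  Fs$spec <- Fs$spec * fit$gain
  Fn$spec <- Fn$spec * fit$gain
  list(s_hat = istft_overlap_add(Fs), n_hat = istft_overlap_add(Fn))
}

# zero-phase band-pass through one CI band (order-4 Butterworth)
band_filter <- function(x, lo, hi, fs) {
  flt <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(flt, x)
}

#' Band-weighted and broadband SNR improvement
#'
#' Computes the input SNR from the scene's clean components at microphone 1
#' and the output SNR from the shadow-decomposed components, both broadband
#' and (optionally) per CI band, and reports the weighted Delta-SNR
#' \deqn{\Delta SNR = \sum_j w_j (SNR_{j,out} - SNR_{j,in})}
#' alongside the unweighted broadband difference.
#'
#' @param scene A `scene_session`.
#' @param s_hat,n_hat Shadow-decomposed output components (from
#'   [shadow_decompose()]).
#' @param band_weights Non-negative weights summing to 1 (default uniform
#'   over the 16 bands).
#' @param table A `band_table` describing the filter bank.
#' @param bands If `FALSE`, skip the per-band analysis and report only the
#'   broadband quantities.
#' @return An object of class `metrics_report`: `snr_in_db`, `snr_out_db`,
#'   `delta_snr_db` (broadband), and when `bands = TRUE` the per-band SNRs
#'   and `delta_snr_weighted_db`.
#' @export
delta_snr <- function(scene, s_hat, n_hat, band_weights = NULL,
                      table = build_default_band_table(), bands = TRUE) {
  stopifnot(inherits(scene, "scene_session"))
  s <- scene$speech_mic1$samples
  n <- scene$noise_mic1$samples
  sh <- s_hat$samples
  nh <- n_hat$samples
  fs <- scene$mic1$fs
  rep <- list(snr_in_db = 10 * log10(sum(s^2) / sum(n^2)),
              snr_out_db = 10 * log10(sum(sh^2) / sum(nh^2)))
  rep$delta_snr_db <- rep$snr_out_db - rep$snr_in_db
  if (bands) {
    validate_band_table(table)
    J <- nrow(table)
    if (is.null(band_weights)) band_weights <- rep(1 / J, J)
    if (length(band_weights) != J || any(band_weights < 0) ||
        abs(sum(band_weights) - 1) > 1e-6) {
      stop("band_weights must be non-negative and sum to 1")
    }
    snr_bands <- vapply(seq_len(J), function(j) {
      lo <- table$lo_hz[j]; hi <- table$hi_hz[j]
      c(in_db = 10 * log10(sum(band_filter(s, lo, hi, fs)^2) /
                             sum(band_filter(n, lo, hi, fs)^2)),
        out_db = 10 * log10(sum(band_filter(sh, lo, hi, fs)^2) /
                              sum(band_filter(nh, lo, hi, fs)^2)))
    }, numeric(2))
    rep$snr_band_in_db <- snr_bands["in_db", ]
    rep$snr_band_out_db <- snr_bands["out_db", ]
    rep$band_weights <- band_weights
    rep$delta_snr_weighted_db <-
      sum(band_weights * (snr_bands["out_db", ] - snr_bands["in_db", ]))
  }
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> SNR in %.2f dB -> out %.2f dB | broadband dSNR %.2f dB\n",
              x$snr_in_db, x$snr_out_db, x$delta_snr_db))
  if (!is.null(x$delta_snr_weighted_db)) {
    cat(sprintf("  band-weighted dSNR %.2f dB over %d bands\n",
                x$delta_snr_weighted_db, length(x$band_weights)))
  }
  if (!is.null(x$distortion_index_db)) {
    cat(sprintf("  speech distortion index %.2f dB\n", x$distortion_index_db))
  }
  invisible(x)
}

#' Speech distortion index in dB
#'
#' Spectral-domain distortion of the enhanced speech relative to the clean
#' reference. Over speech-active frames, the per-bin effective gain is
#' `h_i = sqrt(sum |E_i|^2 / sum |C_i|^2)`; the index is the clean-power
#' weighted normalized deviation from unit gain,
#' \deqn{v_{sd} = \frac{\sum_i \lambda_i (1 - h_i)^2}{\sum_i \lambda_i}}
#' with `lambda_i` the clean per-bin power, reported as `10 log10(v_sd)`
#' (floored at -60 dB; more negative = less distortion).
#'
#' @param clean,enhanced `audio` objects of equal length.
#' @param frame A `frame_config` for the spectral analysis.
#' @param active Optional logical vector of per-frame speech activity;
#'   defaults to frames whose clean energy is within 40 dB of the loudest
#'   frame (use simulator ground truth when available to decouple the metric
#'   from the detector).
#' @return Distortion index in dB.
#' @export
distortion_index <- function(clean, enhanced, frame = frame_config(),
                             active = NULL) {
  stopifnot(inherits(clean, "audio"), inherits(enhanced, "audio"))
  if (length(clean) != length(enhanced)) stop("signals must have equal length")
  Fc <- stft(clean, frame)
  Fe <- stft(enhanced, frame)
  fe <- colSums(Fc$power)
  if (max(fe) == 0) stop("clean input is silent: distortion index undefined")
  if (is.null(active)) active <- fe >= max(fe) * 1e-4
  if (!any(active)) stop("no speech-active frames")
  Pc <- rowSums(Fc$power[, active, drop = FALSE])
  Pe <- rowSums(Fe$power[, active, drop = FALSE])
  lam <- Pc
  h <- ifelse(Pc > 0, sqrt(Pe / Pc), 0)  # bins with no clean power get zero weight
  v <- sum(lam * (1 - h)^2) / sum(lam)
  max(10 * log10(max(v, 1e-6)), -60)
}
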