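# Noise-directivity estimation: the per-bin power ratio of the two
# differential channels on noise-only frames. For a directional interferer at
# azimuth phi the ratio is nearly frequency-flat and approaches cot^4(phi/2),
# which makes a scalar summary a robust cold-start and lets the azimuth be
# read back from the ratio.

# internal recursive state: exponentially-forgotten per-bin noise powers
dir_state_new <- function(n_bins, forgetting = 0.9) {
  list(p1 = numeric(n_bins), p2 = numeric(n_bins),
       n_frames = 0L, forgetting = forgetting, consec_reject = 0L)
}

dir_state_update <- function(state, p1_frame, p2_frame) {
  if (state$n_frames == 0L) {
    state$p1 <- p1_frame
    state$p2 <- p2_frame
  } else {
    a <- state$forgetting
    state$p1 <- a * state$p1 + (1 - a) * p1_frame
    state$p2 <- a * state$p2 + (1 - a) * p2_frame
  }
  state$n_frames <- state$n_frames + 1L
  state$consec_reject <- 0L
  state
}

# Admission control for directivity updates. Two physics-based guards protect
# the noise profile from frames the cepstral detector mislabels:
#
# 1. Front-null guard: channel 2 nulls the front, so a lateral interferer
#    always shows substantial channel-2 power (P2/P1 = tan^4(phi/2) > 1e-3
#    for phi beyond ~20 degrees). A frame with essentially no channel-2
#    energy is silence or desired speech and never updates the profile.
# 2. Ratio consistency: desired speech adds power to channel 1 only, so a
#    speech-contaminated frame shows a broadband P1/P2 well above the
#    tracked noise ratio. Frames deviating by more than `tol_db` are
#    rejected. After `max_reject` consecutive rejections the acoustic regime
#    has evidently changed (the interferer moved or changed character), so
#    the state is restarted from the current frame rather than blended --
#    a wrong restart heals itself the same way within ~0.25 s once a stable
#    regime returns, whereas blending would lock in the contamination.
# Returns list(state, admitted, pure_noise): `admitted` = the frame updated
# the profile; `pure_noise` = the frame additionally sits inside the tight
# consistency band (`pure_tol_db`), i.e. its broadband ratio is
# indistinguishable from the tracked noise ratio, so it carries no
# appreciable desired-speech power.
dir_state_consider <- function(state, p1_frame, p2_frame, guard = 1e-3,
                               tol_db = 6, pure_tol_db = 2.5,
                               min_frames = 5L, max_reject = 20L) {
  e1 <- sum(p1_frame)
  e2 <- sum(p2_frame)
  if (!(e1 > 0 && e2 >= guard * e1)) {
    return(list(state = state, admitted = FALSE, pure_noise = FALSE))
  }
  pure <- TRUE
  if (state$n_frames >= min_frames) {
    ref <- sum(state$p1) / sum(state$p2)
    dev_db <- abs(10 * log10((e1 / e2) / ref))
    pure <- dev_db <= pure_tol_db
    if (dev_db > tol_db) {
      if (state$consec_reject < max_reject) {
        state$consec_reject <- state$consec_reject + 1L
        return(list(state = state, admitted = FALSE, pure_noise = FALSE))
      }
      state <- dir_state_new(length(state$p1), state$forgetting)
      pure <- FALSE
    }
  }
  list(state = dir_state_update(state, p1_frame, p2_frame),
       admitted = TRUE, pure_noise = pure)
}

dir_state_ratio <- function(state) {
  eps <- 1e-12 * mean(state$p1 + state$p2) + 1e-300
  (state$p1 + eps) / (state$p2 + eps)
}

# energy-weighted median of the per-bin ratios over a frequency band
dir_state_scalar <- function(state, freqs, band = c(300, 5000)) {
  sel <- freqs >= band[1] & freqs <= band[2]
  r <- dir_state_ratio(state)[sel]
  w <- (state$p1 + state$p2)[sel]
  if (sum(w) == 0) return(1)
  weighted_median(r, w)
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

#' Estimate the noise directivity profile
#'
#' Accumulates exponentially-forgotten averages of the two channels' power
#' spectra over the noise-only frames and forms the per-bin ratio
#' E|CH1|^2 / E|CH2|^2 (epsilon-regularized). The scalar summary is the
#' energy-weighted median of the per-bin ratios over 300-5000 Hz, and the
#' noise azimuth estimate is its cot^4(phi/2) inversion. The recursive update
#' (forgetting 0.9 per noise frame) lets the profile track a moving
#' interferer.
#'
#' @param ch1_frames,ch2_frames `spectral_frames` of the two differential
#'   channels.
#' @param labels A `frame_labels` object (from [classify_frames()]).
#' @param forgetting Exponential forgetting weight per noise frame (0.9).
#' @return An object of class `directivity_profile` with `ratio_per_bin`,
#'   `scalar_ratio`, `azimuth_deg_est`, `frames_used`, `forgetting`.
#' @export
estimate_directivity <- function(ch1_frames, ch2_frames, labels,
                                 forgetting = 0.9) {
  stopifnot(inherits(ch1_frames, "spectral_frames"),
            inherits(ch2_frames, "spectral_frames"),
            inherits(labels, "frame_labels"))
  if (!any(labels$noise_only)) stop("directivity unavailable: no noise-only frames")
  st <- dir_state_new(nrow(ch1_frames$power), forgetting)
  for (j in which(labels$noise_only)) {
    st <- dir_state_consider(st, ch1_frames$power[, j],
                             ch2_frames$power[, j])$state
  }
  if (st$n_frames == 0L) stop("directivity unavailable: no admissible noise-only frames")
  scalar <- dir_state_scalar(st, ch1_frames$freqs)
  structure(list(ratio_per_bin = dir_state_ratio(st),
                 scalar_ratio = scalar,
                 azimuth_deg_est = directivity_to_azimuth(scalar),
                 frames_used = st$n_frames,
                 forgetting = forgetting),
            class = "directivity_profile")
}

#' @export
print.directivity_profile <- function(x, ...) {
  cat(sprintf(
    "<directivity_profile> scalar ratio %.4g (azimuth est. %.1f deg) from %d noise frames\n",
    x$scalar_ratio, x$azimuth_deg_est, x$frames_used))
  invisible(x)
}

#' Invert a directivity ratio to a noise azimuth
#'
#' Solves `ratio = cot^4(phi/2)` for phi:
#' `phi = 2 atan(ratio^(-1/4))`, in degrees, in (0, 180).
#'
#' @param ratio Linear power ratio (> 0).
#' @return Azimuth in degrees.
#' @examples
#' directivity_to_azimuth(1)    # 90
#' directivity_to_azimuth(1/9)  # 120
#' @export
directivity_to_azimuth <- function(ratio) {
  if (!is.numeric(ratio) || any(ratio <= 0)) stop("ratio must be > 0")
  2 * atan(ratio^(-1 / 4)) * 180 / pi
}
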