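# Cepstral noise-frame detection. The real cepstrum of each frame's power
# spectrum is compared against a tracked noise template; frames whose
# cepstral distance stays under a threshold are declared noise-only and feed
# the directivity estimator.

#' Cepstral tracker configuration / state
#'
#' Holds the tracked low-order cepstrum of the noise and the detection
#' parameters: the smoothing weight beta of the template update
#' `C_i = beta C_i + (1 - beta) C_{i-1}` (0.85), the number of retained
#' coefficients p, the leading-term weight A of the distance
#' \deqn{d_{cep} = A (c_0' - c_0)^2 + 2 \sum_{n=1}^{p} (c_n' - c_n)^2,}
#' and the decision threshold (when `NULL`, it is auto-calibrated from the
#' initialization frames as mean + k sd of their distances).
#'
#' @param beta Template update weight in (0, 1), default 0.85.
#' @param p Number of retained cepstral coefficients beyond c0, default 12.
#' @param scale_A Weight of the c0 term in the distance, default 1.
#' @param threshold Distance threshold (> 0), or `NULL` for auto-calibration.
#' @param k_auto Multiplier of the initialization-distance spread used by the
#'   auto threshold, default 3.
#' @return An object of class `cepstral_tracker`.
#' @export
cepstral_tracker <- function(beta = 0.85, p = 12, scale_A = 1,
                             threshold = NULL, k_auto = 3) {
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)")
  if (p < 1) stop("p must be >= 1")
  if (!is.null(threshold) && threshold <= 0) stop("threshold must be > 0")
  structure(list(beta = beta, p = as.integer(p), scale_A = scale_A,
                 threshold = threshold, k_auto = k_auto,
                 cepstrum = NULL),
            class = "cepstral_tracker")
}

# real cepstrum (coefficients c0..cp) of a one-sided power spectrum; NULL for
# an all-zero (silent) frame
frame_cepstrum <- function(frame_power, p) {
  mx <- max(frame_power)
  if (mx == 0) return(NULL)
  lg <- log(pmax(frame_power, mx * 1e-12))
  nb <- length(lg)
  full <- c(lg, lg[(nb - 1L):2L])
  ce <- Re(stats::fft(full, inverse = TRUE)) / length(full)
  ce[seq_len(p + 1L)]
}

cep_distance <- function(c_new, c_old, scale_A) {
  d0 <- (c_new[1] - c_old[1])^2
  scale_A * d0 + 2 * sum((c_new[-1] - c_old[-1])^2)
}

#' Update the cepstral tracker with one frame
#'
#' Computes the frame's truncated real cepstrum, its cepstral distance to the
#' tracked template (returned before blending), then blends the template
#' toward the frame with weight beta. An all-zero spectrum is flagged silent:
#' distance 0, tracker unchanged.
#'
#' @param tracker A `cepstral_tracker` (its `cepstrum` field carries state).
#' @param frame_power Non-negative one-sided power spectrum of one frame.
#' @return A list with elements `tracker` (updated), `distance`, `silent`.
#' @export
update_cepstrum <- function(tracker, frame_power) {
  stopifnot(inherits(tracker, "cepstral_tracker"))
  if (any(frame_power < 0)) stop("frame_power must be non-negative")
  ce <- frame_cepstrum(frame_power, tracker$p)
  if (is.null(ce)) {
    return(list(tracker = tracker, distance = 0, silent = TRUE))
  }
  if (is.null(tracker$cepstrum)) {
    tracker$cepstrum <- ce
    return(list(tracker = tracker, distance = 0, silent = FALSE))
  }
  d <- cep_distance(ce, tracker$cepstrum, tracker$scale_A)
  tracker$cepstrum <- (1 - tracker$beta) * ce + tracker$beta * tracker$cepstrum
  list(tracker = tracker, distance = d, silent = FALSE)
}

# mean + k sd with one outlier-trimming pass and a relative floor
mean_ksd_threshold <- function(d, k) {
  spread <- if (length(d) >= 2) stats::sd(d) else 0
  thr <- mean(d) + k * spread
  keep <- d <= thr
  if (any(keep) && !all(keep)) {
    spread <- if (sum(keep) >= 2) stats::sd(d[keep]) else 0
    thr <- mean(d[keep]) + k * spread
  }
  max(thr, 0.1 * mean(d), 1e-8)
}

#' Classify frames as noise-only or speech
#'
#' The first `n_init` frames are taken as noise (the session's noise-only
#' lead-in), their average cepstrum initializes the template, and the spread
#' of their distances calibrates the threshold (mean + k sd) unless an
#' explicit threshold was configured. Each later frame is noise-only iff its
#' cepstral distance to the template is at or below the threshold; the
#' template is blended (weight beta) only on noise-labeled frames so speech
#' never contaminates it. Silent (all-zero) frames count as noise-only.
#'
#' @param ch1_frames A `spectral_frames` object for differential channel 1.
#' @param tracker_cfg A `cepstral_tracker` configuration.
#' @param n_init Number of initialization frames (default 10, about 0.25 s
#'   of the lead-in at the default framing).
#' @return An object of class `frame_labels`: list with logical vector
#'   `noise_only`, numeric `distances`, and the resolved `threshold`.
#' @export
classify_frames <- function(ch1_frames, tracker_cfg = cepstral_tracker(),
                            n_init = 10) {
  stopifnot(inherits(ch1_frames, "spectral_frames"),
            inherits(tracker_cfg, "cepstral_tracker"))
  nf <- ncol(ch1_frames$power)
  if (nf <= n_init) stop("fewer frames than n_init")
  p <- tracker_cfg$p
  beta <- tracker_cfg$beta
  ceps <- lapply(seq_len(nf),
                 function(j) frame_cepstrum(ch1_frames$power[, j], p))

  # Initialization window: the first n_init frames with signal in them.
  # Silent (all-zero) frames are trivially noise and do not count toward the
  # window, so a digitally silent lead-in defers calibration until the noise
  # actually starts.
  live_idx <- which(!vapply(ceps, is.null, logical(1)))
  init_idx <- utils::head(live_idx, n_init)
  template <- if (length(init_idx)) {
    Reduce(`+`, ceps[init_idx]) / length(init_idx)
  } else NULL

  noise_only <- logical(nf)
  distances <- numeric(nf)

  # Calibration distances are collected the same way live frames are judged:
  # against the running (beta-blended) template, so the threshold matches the
  # operational distance distribution. One trimming pass discards
  # initialization outliers (e.g. a note onset landing in the lead-in) before
  # the mean + k sd rule is applied.
  d_init <- numeric(length(init_idx))
  for (i in seq_along(init_idx)) {
    ce <- ceps[[init_idx[i]]]
    d_init[i] <- cep_distance(ce, template, tracker_cfg$scale_A)
    template <- (1 - beta) * ce + beta * template
  }
  threshold <- tracker_cfg$threshold
  if (is.null(threshold)) {
    threshold <- if (length(d_init)) {
      mean_ksd_threshold(d_init, tracker_cfg$k_auto)
    } else 1e-8
  }

  init_end <- if (length(init_idx)) max(init_idx) else nf
  noise_only[seq_len(init_end)] <- TRUE
  distances[init_idx] <- d_init
  for (j in seq_len(nf)[-seq_len(init_end)]) {
    ce <- ceps[[j]]
    if (is.null(ce)) {            # silent frame
      noise_only[j] <- TRUE
      next
    }
    d <- cep_distance(ce, template, tracker_cfg$scale_A)
    distances[j] <- d
    if (d <= threshold) {
      noise_only[j] <- TRUE
      template <- (1 - beta) * ce + beta * template
    }
  }
  structure(list(noise_only = noise_only, distances = distances,
                 threshold = threshold),
            class = "frame_labels")
}

#' @export
print.frame_labels <- function(x, ...) {
  cat(sprintf("<frame_labels> %d frames: %d noise-only, %d speech (threshold %.3g)\n",
              length(x$noise_only), sum(x$noise_only), sum(!x$noise_only),
              x$threshold))
  invisible(x)
}
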