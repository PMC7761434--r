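#' Simulate two-class motor-imagery EEG trials
#'
#' Generates a balanced, reproducibly shuffled set of two-channel (C3/C4)
#' trials mimicking left/right-hand motor-imagery EEG: each channel is
#' broadband Gaussian noise band-limited to 0.5-30 Hz (zero-phase filtered,
#' as in typical pre-filtered recordings) plus a narrowband mu rhythm
#' (8-12 Hz). During the imagery window the mu amplitude of the
#' class-contralateral channel is multiplied by `1 - erd_depth` (ERD) and
#' that of the ipsilateral channel by `1 + erd_depth` (ERS), so the
#' channel-wise entropy trajectories diverge between classes. The gain is
#' applied to the mu component only; the broadband noise is untouched, so
#' the contrast is band-specific as in real ERD. With `erd_depth = 0` the
#' label carries no information (a null pipeline check).
#'
#' The first channel is treated as the left-hemisphere site (C3), the
#' second as the right-hemisphere site (C4); left-hand imagery attenuates
#' the mu rhythm on the contralateral C4 and enhances it on C3, and
#' conversely for right-hand imagery.
#'
#' @param n_trials_per_class Trials per class (default 140, i.e. 280 total).
#' @param fs Sampling rate in Hz.
#' @param duration_s Trial duration in seconds; `fs * duration_s` must be
#'   a whole number of samples.
#' @param channels Two channel labels, left hemisphere first.
#' @param mu_band Mu-rhythm band `c(low, high)` in Hz.
#' @param mu_amp Standard deviation of the unmodulated mu component.
#' @param erd_depth Fractional mu-amplitude modulation in `[0, 1)`.
#' @param erd_onset_s,erd_offset_s Imagery-modulation window in seconds
#'   (defaults 3.5 and 7, i.e. samples 449-896 at 128 Hz).
#' @param noise_sd Standard deviation of the broadband noise before
#'   band-limiting.
#' @param seed Integer seed; the whole dataset is a pure function of it.
#' @return A long tibble with columns `trial` (integer id), `label`
#'   (factor, "left"/"right"), `channel`, `sample` (1-based), `value`.
#' @examples
#' tr <- simulate_mi_eeg(n_trials_per_class = 2, seed = 1)
#' dplyr::count(tr, label) # balanced
#' @export
simulate_mi_eeg <- function(n_trials_per_class = 140, fs = 128,
                            duration_s = 9, channels = c("C3", "C4"),
                            mu_band = c(8, 12), mu_amp = 1,
                            erd_depth = 0.5, erd_onset_s = 3.5,
                            erd_offset_s = 7, noise_sd = 1, seed = 0) {
  n_per <- check_count(n_trials_per_class, "n_trials_per_class")
  check_sim_config(fs, duration_s, channels, mu_band, mu_amp, erd_depth,
                   erd_onset_s, erd_offset_s, noise_sd)
  labels <- rep(c("left", "right"), each = n_per)
  withr::with_seed(as.integer(seed), {
    mats <- lapply(labels, function(lab) {
      sim_trial_matrix(lab, fs, duration_s, channels, mu_band, mu_amp,
                       erd_depth, erd_onset_s, erd_offset_s, noise_sd)
    })
    ord <- sample.int(length(labels))
  })
  ns <- as.integer(round(fs * duration_s))
  purrr::map2_dfr(seq_along(ord), ord, function(id, src) {
    tibble::tibble(
      trial = id,
      label = factor(labels[src], levels = c("left", "right")),
      channel = rep(channels, each = ns),
      sample = rep(seq_len(ns), times = length(channels)),
      value = as.numeric(t(mats[[src]]))
    )
  })
}

#' Simulate a single motor-imagery trial
#'
#' One trial of the generator behind [simulate_mi_eeg()], for a given class
#' label and seed. Deterministic: the same arguments always return the same
#' matrix, and with `erd_depth = 0` the label has no effect on the output.
#'
#' @inheritParams simulate_mi_eeg
#' @param label `"left"` or `"right"`.
#' @return A numeric matrix, channels x samples, with channel rownames.
#' @export
simulate_trial <- function(label = c("left", "right"), fs = 128,
                           duration_s = 9, channels = c("C3", "C4"),
                           mu_band = c(8, 12), mu_amp = 1, erd_depth = 0.5,
                           erd_onset_s = 3.5, erd_offset_s = 7,
                           noise_sd = 1, seed = 0) {
  label <- match.arg(label)
  check_sim_config(fs, duration_s, channels, mu_band, mu_amp, erd_depth,
                   erd_onset_s, erd_offset_s, noise_sd)
  withr::with_seed(as.integer(seed), {
    sim_trial_matrix(label, fs, duration_s, channels, mu_band, mu_amp,
                     erd_depth, erd_onset_s, erd_offset_s, noise_sd)
  })
}

# Draws from the current RNG stream: broadband + mu noise per channel,
# then the class-dependent mu gain inside the imagery window.
sim_trial_matrix <- function(label, fs, duration_s, channels, mu_band,
                             mu_amp, erd_depth, erd_onset_s, erd_offset_s,
                             noise_sd) {
  ns <- as.integer(round(fs * duration_s))
  nyq <- fs / 2
  bb_filt <- signal::butter(4, c(0.5, 30) / nyq, type = "pass")
  mu_filt <- signal::butter(4, mu_band / nyq, type = "pass")
  w1 <- as.integer(floor(erd_onset_s * fs)) + 1L
  w2 <- as.integer(floor(erd_offset_s * fs))
  window <- seq(w1, min(w2, ns))
  # contralateral channel: right hemisphere (channel 2) for left-hand imagery
  contra <- if (label == "left") 2L else 1L
  ipsi <- 3L - contra

  out <- matrix(0, nrow = length(channels), ncol = ns,
                dimnames = list(channels, NULL))
  for (ch in seq_along(channels)) {
    noise <- signal::filtfilt(bb_filt, rnorm(ns, sd = noise_sd))
    mu <- signal::filtfilt(mu_filt, rnorm(ns))
    mu <- mu * (mu_amp / pop_sd(mu))
    gain <- rep(1, ns)
    if (erd_depth > 0) {
      gain[window] <- if (ch == contra) 1 - erd_depth else 1 + erd_depth
    }
    out[ch, ] <- noise + gain * mu
  }
  out
}

check_sim_config <- function(fs, duration_s, channels, mu_band, mu_amp,
                             erd_depth, erd_onset_s, erd_offset_s,
                             noise_sd) {
  if (!is.numeric(fs) || fs <= 0) abort("fs must be positive")
  ns <- fs * duration_s
  if (abs(ns - round(ns)) > 1e-9 || ns < 1) {
    abort("fs * duration_s must be a positive whole number of samples")
  }
  if (length(channels) != 2L) abort("exactly two channels are supported")
  if (length(mu_band) != 2L || mu_band[1] <= 0 || mu_band[2] <= mu_band[1] ||
      mu_band[2] >= fs / 2) {
    abort("mu_band must be c(low, high) with 0 < low < high < fs/2")
  }
  if (!is.numeric(erd_depth) || erd_depth < 0 || erd_depth >= 1) {
    abort("erd_depth must lie in [0, 1)")
  }
  if (erd_onset_s >= erd_offset_s || erd_offset_s > duration_s) {
    abort("need erd_onset_s < erd_offset_s <= duration_s")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0 || !is.numeric(mu_amp) ||
      mu_amp < 0) {
    abort("noise_sd and mu_amp must be non-negative")
  }
  invisible(TRUE)
}
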