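#' Crop trials to a sampling interval
#'
#' Restricts every trial to the inclusive 1-based sample interval
#' `[b, d]` (length `H = d - b + 1`). For the standard 9-s, 128-Hz
#' motor-imagery layout the shipped default `[450, 900]` covers the period
#' where the class-dependent ERD/ERS contrast between C3 and C4 is
#' strongest, giving `H = 451`.
#'
#' @param trials A long-format trial tibble with columns `trial`, `channel`,
#'   `sample` (1-based index), `value`, and optionally `label`.
#' @param interval Length-2 integer vector `c(b, d)`.
#' @return The filtered tibble (original `sample` indices retained).
#' @examples
#' tr <- simulate_mi_eeg(n_trials_per_class = 1, seed = 1)
#' nrow(crop_trials(tr)) / 2  # 451 samples per channel
#' @export
crop_trials <- function(trials, interval = c(450, 900)) {
  check_trials(trials)
  if (length(interval) != 2L || !all(is.finite(interval)) ||
      interval[1] > interval[2] || interval[1] < 1) {
    abort("interval must be c(b, d) with 1 <= b <= d")
  }
  n_max <- max(trials$sample)
  if (interval[2] > n_max) {
    abort(sprintf("interval [%d, %d] out of bounds: trials have %d samples",
                  interval[1], interval[2], n_max))
  }
  dplyr::filter(trials, .data$sample >= interval[1],
                .data$sample <= interval[2])
}

#' Fused multi-channel multi-scale entropy features
#'
#' Computes the WCMFE of every channel at every scale 1..`tau_max` and
#' fuses them, scale-major, into one feature vector per trial:
#' `F = [F1, ..., F_tau_max]` with `F_tau = (WCMFE_tau of ch1, ch2, ...)`.
#' For two channels and `tau_max = 7` this is the 14-dimensional vector fed
#' to the classifier. Pass trials through [crop_trials()] first; the
#' similarity tolerance is resolved per channel per trial from the cropped
#' signal and shared across scales.
#'
#' @inheritParams crop_trials
#' @inheritParams wcmfe
#' @param tau_max Maximum scale factor.
#' @param weights `"wcmfe"` for the symmetric weights of mode `h`,
#'   `"uniform"` for plain-mean coarse-graining (CMFE features).
#' @return A tibble with one row per trial: `trial`, `label` (if present),
#'   then columns `s{tau}_{channel}` ordered scale-major with channels in
#'   their order of first appearance.
#' @examples
#' tr <- crop_trials(simulate_mi_eeg(n_trials_per_class = 2, seed = 1))
#' feats <- extract_features(tr, tau_max = 2)
#' names(feats)
#' @export
extract_features <- function(trials, tau_max = 7, h = 3, m = 2, n = 2,
                             r = 0.15, weights = c("wcmfe", "uniform"),
                             literal_scaling = FALSE) {
  check_trials(trials)
  weights <- match.arg(weights)
  tau_max <- check_count(tau_max, "tau_max")
  channels <- unique(trials$channel)
  has_label <- "label" %in% names(trials)

  long <- trials |>
    dplyr::group_by(.data$trial, .data$channel) |>
    dplyr::arrange(.data$sample, .by_group = TRUE) |>
    dplyr::reframe(scale = seq_len(tau_max), value = {
      x <- .data$value
      vapply(seq_len(tau_max), function(tau) {
        wv <- if (weights == "uniform") uniform_weights(tau) else
          make_weights(tau, h)
        tryCatch(
          wcmfe(x, tau = tau, weights = wv, m = m, n = n, r = r,
                literal_scaling = literal_scaling),
          error = function(e) {
            abort(sprintf("feature extraction failed (trial %s, channel %s, tau %d): %s",
                          as.character(.data$trial[1]),
                          as.character(.data$channel[1]), tau,
                          conditionMessage(e)))
          }
        )
      }, numeric(1))
    })

  long$feature <- factor(
    paste0("s", long$scale, "_", long$channel),
    levels = as.vector(t(outer(paste0("s", seq_len(tau_max), "_"),
                               channels, paste0)))
  )
  wide <- long |>
    dplyr::select("trial", "feature", "value") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value",
                       names_expand = TRUE)
  if (has_label) {
    labels <- dplyr::distinct(trials, .data$trial, .data$label)
    wide <- dplyr::left_join(labels, wide, by = "trial")
  }
  wide
}

#' Sliding-window mean entropy curves
#'
#' For every class label, slides a window along each trial of one channel,
#' computes the entropy of the windowed segment at scale `tau`, and averages
#' across the class's trials. The resulting curves visualise how the
#' entropy of C3 and C4 diverges between left- and right-hand imagery
#' (the ERD/ERS signature) and are the basis of interval selection.
#'
#' @inheritParams extract_features
#' @param channel Channel name to analyse.
#' @param fs Sampling rate in Hz (converts `window_s` to samples).
#' @param window_s Window length in seconds (default 1).
#' @param step Step between window starts, in samples (default 1).
#' @param tau Scale factor for the windowed entropy (default 2).
#' @param method `"cmfe"` or `"wcmfe"`.
#' @return A tibble with columns `label`, `start` (1-based window start
#'   sample), `value` (class-mean entropy) and `n_trials`. Curve length is
#'   `floor((N - window) / step) + 1` per class.
#' @export
mean_entropy_curve <- function(trials, channel, fs = 128, window_s = 1,
                               step = 1, tau = 2, m = 2, n = 2, r = 0.15,
                               method = c("cmfe", "wcmfe"), h = 3) {
  check_trials(trials, need_label = TRUE)
  method <- match.arg(method)
  step <- check_count(step, "step")
  tau <- check_count(tau, "tau")
  ch <- dplyr::filter(trials, .data$channel == !!channel)
  if (nrow(ch) == 0) abort(sprintf("channel '%s' not found", channel))
  win <- as.integer(round(window_s * fs))
  lens <- ch |> dplyr::count(.data$trial)
  if (dplyr::n_distinct(lens$n) != 1L) {
    abort("all trials must have the same length")
  }
  N <- lens$n[1]
  if (win > N) abort("window longer than the trials")
  starts <- seq(1L, N - win + 1L, by = step)

  per_trial <- ch |>
    dplyr::group_by(.data$label, .data$trial) |>
    dplyr::arrange(.data$sample, .by_group = TRUE) |>
    dplyr::reframe(start = starts, value = {
      x <- .data$value
      vapply(starts, function(s) {
        seg <- x[s:(s + win - 1L)]
        if (is_constant(seg)) return(0)
        if (method == "cmfe") {
          cmfe(seg, tau = tau, m = m, n = n, r = r)
        } else {
          wcmfe(seg, tau = tau, h = h, m = m, n = n, r = r)
        }
      }, numeric(1))
    })

  per_trial |>
    dplyr::group_by(.data$label, .data$start) |>
    dplyr::summarise(value = mean(.data$value),
                     n_trials = dplyr::n(), .groups = "drop")
}

#' Select the interval of maximal class contrast
#'
#' Given the two class-mean entropy curves, finds the contiguous interval of
#' the requested length that maximises the mean absolute difference between
#' them — an explicit stand-in for choosing "where the curves differ most"
#' by eye. Deterministic; ties resolve to the earliest start.
#'
#' @param curve1,curve2 Numeric vectors of equal length (class-mean entropy
#'   per window start).
#' @param length Interval length in curve samples.
#' @return A one-row tibble with `b`, `d` (1-based inclusive bounds into the
#'   curves) and `score` (the achieved mean absolute difference).
#' @examples
#' select_interval(c(0, 0, 1, 1, 0), c(0, 0, 0, 0, 0), length = 2)
#' @export
select_interval <- function(curve1, curve2, length) {
  check_sequence(curve1, "curve1")
  check_sequence(curve2, "curve2")
  if (base::length(curve1) != base::length(curve2)) {
    abort("curves must have equal length")
  }
  L <- check_count(length, "length")
  n <- base::length(curve1)
  if (L > n) abort(sprintf("interval length %d exceeds curve length %d", L, n))
  d <- abs(curve1 - curve2)
  cs <- c(0, cumsum(d))
  scores <- (cs[(L + 1):(n + 1)] - cs[1:(n - L + 1)]) / L
  b <- which.max(scores)  # first maximum -> earliest tie-break
  tibble::tibble(b = b, d = b + L - 1L, score = scores[b])
}

#' Per-class statistics of the C3 - C4 entropy difference
#'
#' For each trial, takes the difference between the entropy values of two
#' channels (conventionally C3 minus C4) and summarises it per class:
#' `mwc` is the class mean of the differences and `sdwc` their population
#' standard deviation. A large between-class gap in `mwc` with small `sdwc`
#' indicates good separability; the sign of `mwc` flips between left- and
#' right-hand imagery.
#'
#' @param data A data frame with one row per trial.
#' @param c3,c4 Columns (tidy-select) holding the per-trial entropy of the
#'   two channels.
#' @param label Column holding the class label.
#' @return A tibble with columns `label`, `mwc`, `sdwc`, `n`.
#' @examples
#' df <- tibble::tibble(lab = c("a", "a"), x3 = c(2, 4), x4 = c(1, 1))
#' dwc_stats(df, x3, x4, lab)  # mwc 2, sdwc 1
#' @export
dwc_stats <- function(data, c3, c4, label) {
  if (!is.data.frame(data)) abort("data must be a data frame")
  out <- data |>
    dplyr::mutate(.dwc = {{ c3 }} - {{ c4 }}) |>
    dplyr::group_by(label = {{ label }}) |>
    dplyr::summarise(mwc = mean(.data$.dwc),
                     sdwc = pop_sd(.data$.dwc),
                     n = dplyr::n(), .groups = "drop")
  if (any(!is.finite(out$mwc))) abort("non-finite entropy differences")
  out
}

check_trials <- function(trials, need_label = FALSE) {
  if (!is.data.frame(trials)) abort("trials must be a data frame")
  need <- c("trial", "channel", "sample", "value")
  if (need_label) need <- c(need, "label")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    abort(sprintf("trials is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(trials) == 0) abort("trials is empty")
  invisible(trials)
}
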