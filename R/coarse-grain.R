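#' Weighted coarse-graining of a signal
#'
#' Reduces a signal at scale `tau` by replacing each window of `tau`
#' consecutive samples with its weighted mean. Offset `k` in 1..`tau` shifts
#' the window grid, so the `tau` offsets together retain all the phase
#' information a single coarse-graining discards (the "composite" idea).
#' Window `j` of offset `k` covers samples `(j-1)*tau + k` to `j*tau + k - 1`;
#' windows that would extend past the end of the signal are dropped, so
#' offsets can differ in length by one element.
#'
#' @param x Numeric signal.
#' @param tau Scale factor (window length), positive integer.
#' @param k Offset in 1..`tau`.
#' @param weights Weight vector of length `tau` summing to 1; defaults to
#'   the uniform weights (plain moving average).
#' @return Numeric vector of weighted window means, length
#'   `floor((length(x) - k + 1) / tau)`.
#' @examples
#' coarse_grain(1:6, tau = 2)                      # 1.5 3.5 5.5
#' coarse_grain(1:3, tau = 3, weights = make_weights(3, 3))  # 2
#' @export
coarse_grain <- function(x, tau, k = 1, weights = uniform_weights(tau)) {
  check_sequence(x)
  tau <- check_count(tau, "tau")
  k <- check_count(k, "k")
  if (k > tau) abort(sprintf("offset k = %d out of range 1..tau = %d", k, tau))
  w <- check_weights(weights, tau)
  n_win <- (length(x) - k + 1L) %/% tau
  if (n_win < 1L) {
    abort(sprintf("signal too short for tau = %d, k = %d (length %d)",
                  tau, k, length(x)))
  }
  seg <- matrix(x[k:(k + n_win * tau - 1L)], nrow = tau)
  as.numeric(colSums(w * seg))
}

#' Weighted composite multiscale fuzzy entropy at one scale
#'
#' WCMFE of a signal at scale `tau`: the arithmetic mean, over the `tau`
#' coarse-graining offsets, of the fuzzy entropy of each weighted
#' coarse-grained sequence. With uniform weights this reduces exactly to
#' composite multiscale fuzzy entropy (CMFE); with the symmetric weights of
#' [make_weights()] the within-window mean becomes a linear-phase FIR
#' low-pass better matched to nonstationary EEG.
#'
#' The similarity tolerance is resolved once as `r` times the population SD
#' of the supplied (already cropped) signal and shared by all offsets and
#' scales computed from it — the dominant multiscale-entropy convention.
#' Set `r_scope = "sequence"` to recompute it per coarse-grained sequence
#' instead, or pass `r_abs` directly.
#'
#' The printed definition of the weighted coarse-grained value carries both
#' a `1/tau` prefactor and weights that sum to 1; applied literally the two
#' normalisations stack, shrinking every coarse-grained sample by `tau`
#' relative to the plain-mean baseline. The default drops the extra `1/tau`
#' so that uniform weights reproduce CMFE bit-for-bit; `literal_scaling =
#' TRUE` restores the stacked form.
#'
#' @inheritParams coarse_grain
#' @inheritParams fuzzy_entropy
#' @param h Weight mode in 1..4, used when `weights` is not supplied.
#' @param r_scope `"signal"` (default): one tolerance from the input signal
#'   shared by all offsets; `"sequence"`: tolerance recomputed from each
#'   coarse-grained sequence.
#' @param literal_scaling Apply the additional `1/tau` factor to each
#'   coarse-grained value (off by default; see Details).
#' @return A single non-negative number.
#' @examples
#' x <- sin(seq(0, 20 * pi, length.out = 451)) + rnorm(451, sd = 0.3)
#' wcmfe(x, tau = 3)
#' cmfe(x, tau = 3)
#' @export
wcmfe <- function(x, tau, h = 3, weights = make_weights(tau, h),
                  m = 2, n = 2, r = 0.15, r_abs = NULL,
                  r_scope = c("signal", "sequence"),
                  literal_scaling = FALSE) {
  check_sequence(x)
  tau <- check_count(tau, "tau")
  r_scope <- match.arg(r_scope)
  w <- check_weights(weights, tau)
  if (is.null(r_abs) && r_scope == "signal" && !is_constant(x)) {
    r_abs <- r * pop_sd(x)
  }
  fes <- vapply(seq_len(tau), function(k) {
    y <- coarse_grain(x, tau = tau, k = k, weights = w)
    if (literal_scaling) y <- y / tau
    tryCatch(
      fuzzy_entropy(y, m = m, n = n, r = r, r_abs = r_abs),
      error = function(e) {
        abort(sprintf("fuzzy entropy failed at tau = %d, k = %d: %s",
                      tau, k, conditionMessage(e)))
      }
    )
  }, numeric(1))
  mean(fes)
}

#' Composite multiscale fuzzy entropy at one scale
#'
#' CMFE is [wcmfe()] with uniform weights (the plain moving-average
#' coarse-graining); the two share one code path.
#'
#' @inheritParams wcmfe
#' @return A single non-negative number.
#' @export
cmfe <- function(x, tau, m = 2, n = 2, r = 0.15, r_abs = NULL,
                 r_scope = c("signal", "sequence")) {
  wcmfe(x, tau = tau, weights = uniform_weights(tau),
        m = m, n = n, r = r, r_abs = r_abs, r_scope = match.arg(r_scope))
}

#' Multiscale entropy profile of a signal
#'
#' Computes WCMFE (or CMFE) for every scale 1..`tau_max` and returns a tidy
#' table, one row per scale.
#'
#' @inheritParams wcmfe
#' @param tau_max Maximum scale factor.
#' @param method `"wcmfe"` (weighted, mode `h`) or `"cmfe"` (uniform).
#' @return A tibble with columns `scale`, `value`, `method`.
#' @examples
#' wcmfe_profile(rnorm(300), tau_max = 4)
#' @export
wcmfe_profile <- function(x, tau_max = 7, h = 3, m = 2, n = 2, r = 0.15,
                          r_abs = NULL, method = c("wcmfe", "cmfe")) {
  method <- match.arg(method)
  tau_max <- check_count(tau_max, "tau_max")
  vals <- vapply(seq_len(tau_max), function(tau) {
    if (method == "wcmfe") {
      wcmfe(x, tau = tau, h = h, m = m, n = n, r = r, r_abs = r_abs)
    } else {
      cmfe(x, tau = tau, m = m, n = n, r = r, r_abs = r_abs)
    }
  }, numeric(1))
  tibble::tibble(scale = seq_len(tau_max), value = vals, method = method)
}
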