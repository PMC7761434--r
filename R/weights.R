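#' Symmetric coarse-graining weight factors
#'
#' Generates the weight vector `A[tau, h]` used by the weighted
#' coarse-graining step of WCMFE. For `tau > 2` the rule places `h/10` at the
#' two endpoints and spreads the remaining mass uniformly over the
#' `tau - 2` interior taps:
#' `c(h/10, rep((5 - h) / (5 * (tau - 2)), tau - 2), h/10)`.
#' The coefficients are strictly positive, symmetric (hence the filter has
#' linear phase) and sum to 1. The mode `h` in 1..4 trades endpoint versus
#' centre mass and thereby the cut-off of the implied FIR low-pass; `h = 3`
#' is the default used throughout the package.
#'
#' The rule is only defined for `tau > 2`; scales 1 and 2 fall back to the
#' uniform weights `[1]` and `[0.5, 0.5]`, so every scale of a multiscale
#' analysis has a weight vector.
#'
#' @param tau Scale factor (window length), a positive integer.
#' @param h Mode index in 1..4.
#' @return A numeric vector of length `tau` with attributes `tau` and
#'   `mode`, of class `"wcmfe_weights"`.
#' @examples
#' make_weights(3, 1)   # 0.1 0.8 0.1
#' make_weights(5, 4)   # 0.4, three interior taps of 1/15, 0.4
#' @seealso [uniform_weights()], [filter_frequency_response()]
#' @export
make_weights <- function(tau, h = 3) {
  tau <- check_count(tau, "tau")
  if (!is.numeric(h) || length(h) != 1L || !h %in% 1:4) {
    abort("weight mode h must be one of 1, 2, 3, 4")
  }
  h <- as.integer(h)
  w <- if (tau == 1L) {
    1
  } else if (tau == 2L) {
    c(0.5, 0.5)
  } else {
    c(h / 10, rep((5 - h) / (5 * (tau - 2L)), tau - 2L), h / 10)
  }
  new_weights(w, tau = tau, mode = if (tau <= 2L) "uniform" else h)
}

#' Uniform coarse-graining weights
#'
#' The plain moving-average weights `rep(1/tau, tau)`; coarse-graining with
#' these reproduces CMFE exactly.
#'
#' @inheritParams make_weights
#' @return A `"wcmfe_weights"` vector of `tau` equal coefficients.
#' @examples
#' uniform_weights(4)
#' @export
uniform_weights <- function(tau) {
  tau <- check_count(tau, "tau")
  new_weights(rep(1 / tau, tau), tau = tau, mode = "uniform")
}

new_weights <- function(w, tau, mode) {
  structure(as.numeric(w), tau = as.integer(tau), mode = mode,
            class = "wcmfe_weights")
}

#' @export
print.wcmfe_weights <- function(x, ...) {
  cat(sprintf("<wcmfe_weights> tau = %d, mode = %s\n",
              attr(x, "tau"), as.character(attr(x, "mode"))))
  print(as.numeric(x), ...)
  invisible(x)
}

check_weights <- function(weights, tau) {
  w <- as.numeric(weights)
  if (length(w) != tau) {
    abort(sprintf("weight vector has %d coefficients but tau = %d",
                  length(w), tau))
  }
  if (!all(is.finite(w)) || any(w <= 0)) {
    abort("weight coefficients must be finite and positive")
  }
  if (abs(sum(w) - 1) > 1e-8) {
    abort("weight coefficients must sum to 1")
  }
  w
}

#' Frequency response of a weight-factor filter
#'
#' Treats a coarse-graining weight vector as the impulse response of an FIR
#' filter and evaluates its transfer function `H(e^{i*omega})` on a uniform
#' grid over `[0, pi]`. Because the weights sum to 1 the DC gain is exactly
#' 1, and because they are symmetric the filter has linear phase (constant
#' group delay `(tau - 1) / 2` samples): weighted coarse-graining low-pass
#' filters the signal without phase distortion.
#'
#' @param weights A weight vector ([make_weights()], [uniform_weights()], or
#'   any numeric vector of FIR taps).
#' @param n_freqs Number of grid points over `[0, pi]` inclusive.
#' @return A tibble with columns `omega` (rad/sample), `frequency`
#'   (normalised, `omega / pi`), `magnitude` and `phase` (radians).
#' @examples
#' filter_frequency_response(make_weights(3, 1), n_freqs = 5)
#' @export
filter_frequency_response <- function(weights, n_freqs = 512) {
  n_freqs <- check_count(n_freqs, "n_freqs")
  if (n_freqs < 2L) abort("n_freqs must be at least 2")
  w <- as.numeric(weights)
  check_sequence(w, "weights")
  omega <- seq(0, pi, length.out = n_freqs)
  taps <- seq_along(w) - 1L
  H <- vapply(omega, function(o) sum(w * exp(-1i * o * taps)), complex(1))
  tibble::tibble(
    omega = omega,
    frequency = omega / pi,
    magnitude = Mod(H),
    phase = Arg(H)
  )
}
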