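#' Centred delay embedding of a sequence
#'
#' Builds the template vectors used by fuzzy entropy: sliding windows of
#' length `m`, each with its own window mean subtracted, so every template
#' sums to zero. Subtracting the local mean makes the similarity measure
#' insensitive to slow baseline drift, which matters for nonstationary EEG.
#'
#' @param x Numeric vector, length at least `m + 1`.
#' @param m Embedding dimension (template length), a positive integer.
#'
#' @return A numeric matrix with `length(x) - m + 1` rows and `m` columns;
#'   row `i` is `x[i:(i+m-1)] - mean(x[i:(i+m-1)])`.
#' @examples
#' embed_centered(c(1, 2, 3), m = 2)
#' @export
embed_centered <- function(x, m) {
  check_sequence(x)
  m <- check_count(m, "m")
  n <- length(x)
  if (n < m + 1L) {
    abort(sprintf("sequence too short: need length >= m + 1 = %d, got %d",
                  m + 1L, n))
  }
  idx <- outer(seq_len(n - m + 1L) - 1L, seq_len(m), `+`)
  mat <- matrix(x[idx], nrow = n - m + 1L, ncol = m)
  mat - rowMeans(mat)
}

#' Chebyshev distance between two vectors
#'
#' Maximum absolute coordinatewise difference, the metric used to compare
#' centred embedding templates.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A single non-negative number.
#' @examples
#' chebyshev_distance(c(0, 1), c(1, 0))
#' @export
chebyshev_distance <- function(u, v) {
  if (length(u) != length(v)) {
    abort(sprintf("length mismatch: %d vs %d", length(u), length(v)))
  }
  max(abs(u - v))
}

#' Mean fuzzy similarity of embedded templates
#'
#' The similarity statistic underlying fuzzy entropy: the mean, over all
#' ordered pairs of distinct centred `m`-templates, of the fuzzy membership
#' `exp(-d^n / r_abs)` of their Chebyshev distance `d`. For a sequence of
#' length N the first `N - m` templates are used for both dimension `m` and
#' `m + 1`, keeping the pair counts comparable between the two dimensions.
#'
#' @param x Numeric vector, length at least `m + 2`.
#' @param m Embedding dimension.
#' @param n Boundary gradient of the fuzzy membership function (exponent on
#'   the distance); larger values sharpen the similarity boundary.
#' @param r_abs Absolute similarity tolerance (the denominator inside the
#'   exponential); must be positive. Typically `r * SD` of the reference
#'   signal.
#' @return A number in (0, 1]; equals 1 when all templates coincide.
#' @examples
#' fe_phi(rnorm(30), m = 2, n = 2, r_abs = 0.2)
#' @export
fe_phi <- function(x, m = 2, n = 2, r_abs) {
  check_sequence(x)
  m <- check_count(m, "m")
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    abort("boundary gradient n must be a single positive number")
  }
  if (!is.numeric(r_abs) || length(r_abs) != 1L || !is.finite(r_abs) ||
      r_abs <= 0) {
    abort("r_abs must be a single positive number (degenerate tolerance)")
  }
  if (length(x) - m < 2L) {
    abort(sprintf("sequence too short: need length >= m + 2 = %d, got %d",
                  m + 2L, length(x)))
  }
  .phi_kernel(as.numeric(x), as.integer(m), as.numeric(n), as.numeric(r_abs))
}

#' Fuzzy entropy of a sequence
#'
#' Regularity statistic `-ln(phi(m+1) / phi(m))` where `phi` is the mean
#' fuzzy similarity of centred embedding templates ([fe_phi()]). Low values
#' indicate a regular (predictable) signal, high values an irregular one;
#' a constant sequence has entropy exactly 0.
#'
#' The similarity tolerance may be given in absolute form (`r_abs`) or as a
#' multiplier `r` of the population standard deviation of `x` itself. In
#' multiscale use the tolerance is resolved once from the original signal
#' and passed down via `r_abs` (see [wcmfe()]), so all scales share it.
#'
#' @inheritParams fe_phi
#' @param r Relative tolerance: `r_abs` defaults to `r * pop. SD(x)`.
#' @param r_abs Absolute tolerance; overrides `r` when supplied.
#' @return A single non-negative number (`+Inf` with a warning if the
#'   `m + 1` similarity underflows to zero).
#' @examples
#' fuzzy_entropy(sin(seq(0, 8 * pi, length.out = 200)))
#' fuzzy_entropy(rep(1, 50))   # exactly 0
#' @export
fuzzy_entropy <- function(x, m = 2, n = 2, r = 0.15, r_abs = NULL) {
  check_sequence(x)
  m <- check_count(m, "m")
  if (length(x) < m + 3L) {
    abort(sprintf("sequence too short: need length >= m + 3 = %d, got %d",
                  m + 3L, length(x)))
  }
  # A constant sequence is perfectly regular: all template distances are 0,
  # phi(m) = phi(m+1) = 1 for any positive tolerance, so the entropy is 0
  # exactly. Short-circuit so the relative-tolerance resolution (r * SD = 0)
  # cannot poison it.
  if (is_constant(x)) return(0)
  if (is.null(r_abs)) {
    if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
      abort("relative tolerance r must be a single positive number")
    }
    r_abs <- r * pop_sd(x)
  }
  phi_m  <- fe_phi(x, m = m,      n = n, r_abs = r_abs)
  phi_m1 <- fe_phi(x, m = m + 1L, n = n, r_abs = r_abs)
  if (phi_m1 == 0) {
    warn("phi(m+1) underflowed to 0; returning +Inf")
    return(Inf)
  }
  -log(phi_m1 / phi_m)
}

# ---- shared input checks -------------------------------------------------

check_sequence <- function(x, arg = "x") {
  if (!is.numeric(x) || length(x) < 1L) {
    abort(sprintf("%s must be a non-empty numeric vector", arg))
  }
  if (!all(is.finite(x))) {
    abort(sprintf("%s contains non-finite values", arg))
  }
  invisible(x)
}

check_count <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < 1 || x != round(x)) {
    abort(sprintf("%s must be a single positive integer", arg))
  }
  as.integer(x)
}
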