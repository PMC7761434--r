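# Independent brute-force re-implementations of the entropy stack, written
# with explicit loops and no shared code with the package internals. They
# serve as oracles: slow, transparent, and easy to audit.

osd <- function(x) sqrt(mean((x - mean(x))^2))  # population SD

oracle_embed <- function(x, m) {
  out <- list()
  for (i in seq_len(length(x) - m + 1)) {
    w <- x[i:(i + m - 1)]
    out[[i]] <- w - mean(w)
  }
  out
}

oracle_cheb <- function(u, v) {
  d <- 0
  for (l in seq_along(u)) d <- max(d, abs(u[l] - v[l]))
  d
}

# mean over ordered pairs i != j of exp(-d^n / r_abs), first N - m templates
oracle_phi <- function(x, m, n, r_abs) {
  cnt <- length(x) - m
  tmpl <- oracle_embed(x, m)[seq_len(cnt)]
  tot <- 0
  for (i in seq_len(cnt)) {
    for (j in seq_len(cnt)) {
      if (i != j) {
        d <- oracle_cheb(tmpl[[i]], tmpl[[j]])
        tot <- tot + exp(-(d^n) / r_abs)
      }
    }
  }
  tot / (cnt * (cnt - 1))
}

oracle_fe <- function(x, m, n, r_abs) {
  -log(oracle_phi(x, m + 1, n, r_abs) / oracle_phi(x, m, n, r_abs))
}

oracle_coarse <- function(x, tau, k, w) {
  out <- numeric(0)
  j <- 1
  repeat {
    lo <- (j - 1) * tau + k
    hi <- j * tau + k - 1
    if (hi > length(x)) break
    s <- 0
    for (p in seq_len(tau)) s <- s + w[p] * x[lo + p - 1]
    out[j] <- s
    j <- j + 1
  }
  out
}

oracle_wcmfe <- function(x, tau, w, m, n, r) {
  r_abs <- r * osd(x)
  fes <- numeric(tau)
  for (k in seq_len(tau)) {
    fes[k] <- oracle_fe(oracle_coarse(x, tau, k, w), m, n, r_abs)
  }
  mean(fes)
}

# Small synthetic trial set shared by feature-level tests.
small_trial_set <- function(n_per_class = 3, seed = 11, ...) {
  crop_trials(simulate_mi_eeg(n_trials_per_class = n_per_class,
                              seed = seed, ...))
}
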