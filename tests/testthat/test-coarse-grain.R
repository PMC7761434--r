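test_that("weight-factor rule reproduces the published vectors", {
  expect_equal(as.numeric(make_weights(3, 1)), c(0.1, 0.8, 0.1))
  expect_equal(as.numeric(make_weights(3, 2)), c(0.2, 0.6, 0.2))
  expect_equal(as.numeric(make_weights(3, 3)), c(0.3, 0.4, 0.3))
  expect_equal(as.numeric(make_weights(3, 4)), c(0.4, 0.2, 0.4))
  expect_equal(as.numeric(make_weights(5, 1)),
               c(1 / 10, 4 / 15, 4 / 15, 4 / 15, 1 / 10))
  expect_equal(as.numeric(make_weights(5, 4)),
               c(2 / 5, 1 / 15, 1 / 15, 1 / 15, 2 / 5))
})

test_that("weights sum to one, are symmetric and positive for all modes", {
  for (tau in 1:12) {
    for (h in 1:4) {
      w <- as.numeric(make_weights(tau, h))
      expect_length(w, tau)
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_equal(w, rev(w))
      expect_true(all(w > 0))
    }
  }
  expect_equal(as.numeric(make_weights(1, 2)), 1)
  expect_equal(as.numeric(make_weights(2, 4)), c(0.5, 0.5))
  expect_error(make_weights(3, 5), "mode")
  expect_error(make_weights(3, 0), "mode")
})

test_that("uniform weights are 1/tau each", {
  expect_equal(as.numeric(uniform_weights(1)), 1)
  expect_equal(as.numeric(uniform_weights(4)), rep(0.25, 4))
  expect_equal(sum(uniform_weights(7)), 1)
  expect_error(uniform_weights(0), "positive integer")
})

test_that("coarse graining computes weighted window means", {
  expect_equal(coarse_grain(1:6, tau = 2), c(1.5, 3.5, 5.5))
  expect_equal(coarse_grain(1:3, tau = 3, weights = make_weights(3, 3)), 2)
  # weights summing to one preserve a constant signal
  for (tau in c(1, 2, 4)) {
    expect_equal(coarse_grain(rep(4.2, 20), tau, k = min(tau, 2),
                              weights = make_weights(tau, 2)),
                 rep(4.2, length(coarse_grain(rep(4.2, 20), tau,
                                              k = min(tau, 2)))))
  }
  # offsets match the loop oracle, including overrun-window dropping
  x <- withr::with_seed(13, rnorm(23))
  for (tau in 1:5) {
    w <- as.numeric(make_weights(tau, 3))
    for (k in seq_len(tau)) {
      expect_equal(coarse_grain(x, tau, k, make_weights(tau, 3)),
                   oracle_coarse(x, tau, k, w))
    }
  }
  expect_error(coarse_grain(1:10, tau = 2, k = 3), "out of range")
  expect_error(coarse_grain(1:10, tau = 3, weights = c(0.5, 0.5)),
               "coefficients")
  expect_error(coarse_grain(c(1, 2), tau = 5), "too short")
})

test_that("wcmfe at tau = 1 is plain fuzzy entropy", {
  x <- withr::with_seed(17, rnorm(100))
  expect_equal(wcmfe(x, tau = 1), fuzzy_entropy(x))
})

test_that("wcmfe with uniform weights equals cmfe bit for bit", {
  withr::with_seed(19, {
    for (i in 1:5) {
      x <- rnorm(150)
      for (tau in c(1, 3, 5)) {
        expect_identical(wcmfe(x, tau, weights = uniform_weights(tau)),
                         cmfe(x, tau))
      }
    }
  })
})

test_that("wcmfe matches an oracle assembled from the brute-force parts", {
  x <- withr::with_seed(23, rnorm(120))
  expect_equal(wcmfe(x, tau = 3, weights = make_weights(3, 3)),
               oracle_wcmfe(x, 3, as.numeric(make_weights(3, 3)), 2, 2, 0.15),
               tolerance = 1e-10)
})

test_that("cmfe of a constant signal is zero", {
  expect_identical(cmfe(rep(1.5, 60), tau = 3), 0)
})

test_that("the literal double-normalisation flag shrinks the sequences", {
  x <- withr::with_seed(29, rnorm(90))
  expect_equal(coarse_grain(x, 3, weights = make_weights(3, 3)) / 3,
               {
                 w <- as.numeric(make_weights(3, 3))
                 oracle_coarse(x, 3, 1, w) / 3
               })
  # under literal scaling the tau = 1 case is unchanged
  expect_equal(wcmfe(x, tau = 1, literal_scaling = TRUE), wcmfe(x, tau = 1))
})

test_that("coarse-grained variance is non-increasing in tau", {
  # long signals: the tau = 6 -> 7 variance gap is ~3.6% and the sample
  # variance has relative SD sqrt(2/N'), so N' must be >> 1500
  violations <- 0
  for (s in 1:20) {
    x <- withr::with_seed(300 + s, rnorm(131072))
    v <- vapply(1:7, function(tau) {
      var(coarse_grain(x, tau, weights = make_weights(tau, 3)))
    }, numeric(1))
    if (any(diff(v) > 0)) violations <- violations + 1
  }
  expect_lte(violations, 1)
})

test_that("frequency response has unit DC gain and the expected nulls", {
  for (tau in c(2, 3, 5, 7)) {
    for (h in 1:4) {
      resp <- filter_frequency_response(make_weights(tau, h), n_freqs = 64)
      expect_equal(resp$magnitude[1], 1, tolerance = 1e-12)
    }
  }
  two_tap <- filter_frequency_response(c(0.5, 0.5), n_freqs = 33)
  expect_equal(two_tap$magnitude[33], 0, tolerance = 1e-12)
})

test_that("three-tap responses match the closed form", {
  # symmetric taps [a, b, a]: |H| = |b + 2 a cos(omega)|
  for (h in 1:4) {
    w <- as.numeric(make_weights(3, h))
    resp <- filter_frequency_response(w, n_freqs = 128)
    expect_equal(resp$magnitude, abs(w[2] + 2 * w[1] * cos(resp$omega)),
                 tolerance = 1e-12)
  }
})

test_that("symmetric weights give linear phase", {
  for (tau in c(3, 5, 7)) {
    w <- as.numeric(make_weights(tau, 3))
    resp <- filter_frequency_response(w, n_freqs = 256)
    H <- resp$magnitude * exp(1i * resp$phase)
    # remove the constant group delay (tau - 1) / 2; remainder must be real
    residual <- H * exp(1i * resp$omega * (tau - 1) / 2)
    keep <- resp$magnitude > 1e-6
    expect_lt(max(abs(Im(residual[keep]))), 1e-10)
  }
})
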