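make_long_trial <- function(values_by_channel, trial = 1L, label = "left") {
  purrr::imap_dfr(values_by_channel, function(v, ch) {
    tibble::tibble(trial = trial, label = factor(label), channel = ch,
                   sample = seq_along(v), value = v)
  })
}

test_that("cropping keeps the inclusive interval", {
  x <- withr::with_seed(1, rnorm(1152))
  tr <- make_long_trial(list(C3 = x, C4 = rev(x)))
  cr <- crop_trials(tr, c(450, 900))
  expect_equal(nrow(cr), 2 * 451)
  expect_equal(range(cr$sample), c(450, 900))
  expect_equal(cr$value[cr$channel == "C3"], x[450:900])
  single <- crop_trials(tr, c(7, 7))
  expect_equal(nrow(single), 2)
  expect_equal(crop_trials(tr, c(1, 1152)), tr)
  expect_error(crop_trials(tr, c(1, 2000)), "out of bounds")
  expect_error(crop_trials(tr, c(0, 5)), "interval")
})

test_that("feature vectors are nC x tau_max, scale-major", {
  tr <- small_trial_set(n_per_class = 1)
  f <- extract_features(tr, tau_max = 7)
  feat_cols <- setdiff(names(f), c("trial", "label"))
  expect_length(feat_cols, 14)
  expect_equal(feat_cols[1:4], c("s1_C3", "s1_C4", "s2_C3", "s2_C4"))
  expect_true(all(is.finite(as.matrix(f[feat_cols]))))
})

test_that("tau_max = 1 single channel reduces to fuzzy entropy", {
  x <- withr::with_seed(4, rnorm(200))
  tr <- make_long_trial(list(C3 = x))
  f <- extract_features(tr, tau_max = 1)
  expect_equal(f$s1_C3, fuzzy_entropy(x))
})

test_that("identical channels give identical feature blocks", {
  x <- withr::with_seed(5, rnorm(300))
  tr <- make_long_trial(list(C3 = x, C4 = x))
  f <- extract_features(tr, tau_max = 3)
  for (s in 1:3) {
    expect_identical(f[[paste0("s", s, "_C3")]], f[[paste0("s", s, "_C4")]])
  }
})

test_that("extraction is deterministic and respects channel permutation", {
  tr <- small_trial_set(n_per_class = 1)
  f1 <- extract_features(tr, tau_max = 3)
  f2 <- extract_features(tr, tau_max = 3)
  expect_identical(f1, f2)
  # swapping channel order permutes the blocks correspondingly
  swapped <- dplyr::mutate(
    tr, channel = ifelse(channel == "C3", "C4x", "C3x"),
    channel = sub("x$", "", channel))
  fs <- extract_features(dplyr::arrange(swapped, dplyr::desc(channel)),
                         tau_max = 3)
  expect_equal(fs$s2_C3, f1$s2_C4)
  expect_equal(fs$s2_C4, f1$s2_C3)
})

test_that("features are invariant to trial amplitude scaling at n = 1", {
  tr <- small_trial_set(n_per_class = 1)
  f1 <- extract_features(tr, tau_max = 2, n = 1)
  f2 <- extract_features(dplyr::mutate(tr, value = value * 8),
                         tau_max = 2, n = 1)
  cols <- setdiff(names(f1), c("trial", "label"))
  expect_equal(f1[cols], f2[cols], tolerance = 1e-10)
})

test_that("uniform-weight features reproduce CMFE features", {
  tr <- dplyr::filter(small_trial_set(n_per_class = 1), trial == 1)
  fu <- extract_features(tr, tau_max = 3, weights = "uniform")
  x <- dplyr::arrange(dplyr::filter(tr, channel == "C3"), sample)$value
  expect_equal(fu$s3_C3, cmfe(x, 3))
})

test_that("mean entropy curve has the expected length and nulls", {
  const <- make_long_trial(list(C3 = rep(1, 1152), C4 = rep(1, 1152)))
  curve <- mean_entropy_curve(const, "C3", fs = 128, window_s = 1, step = 1)
  expect_equal(nrow(curve), floor((1152 - 128) / 1) + 1)
  expect_true(all(curve$value == 0))
  expect_error(mean_entropy_curve(const, "Cz"), "not found")
})

test_that("class-mean curves separate inside the imagery window", {
  tr <- simulate_mi_eeg(n_trials_per_class = 6, seed = 0)
  curve <- mean_entropy_curve(tr, "C4", fs = 128, step = 16)
  wide <- tidyr::pivot_wider(curve, id_cols = "start",
                             names_from = "label", values_from = "value")
  gap <- abs(wide$left - wide$right)
  inside <- wide$start >= 480 & wide$start <= 760
  before <- wide$start <= 300
  expect_gt(mean(gap[inside]), 2 * mean(gap[before]))
  # and the data-driven interval lands in the modulation window
  sel <- select_interval(wide$left, wide$right, length = 20)
  expect_gte(wide$start[sel$b], 380)
  expect_lte(wide$start[sel$d], 940)
})

test_that("interval selection maximises the mean absolute gap", {
  expect_equal(select_interval(rep(1, 10), rep(1, 10), 3)$b, 1)
  c1 <- c(0, 0, 0, 2, 2, 2, 0, 0)
  sel <- select_interval(c1, rep(0, 8), length = 3)
  expect_equal(sel$b, 4); expect_equal(sel$d, 6); expect_equal(sel$score, 2)
  # exhaustive scan agreement on a random pair
  withr::with_seed(6, {
    a <- rnorm(40); b <- rnorm(40)
  })
  L <- 7
  brute <- vapply(seq_len(40 - L + 1), function(s) {
    mean(abs(a[s:(s + L - 1)] - b[s:(s + L - 1)]))
  }, numeric(1))
  sel <- select_interval(a, b, L)
  expect_equal(sel$b, which.max(brute))
  expect_equal(sel$score, max(brute))
  expect_error(select_interval(a, b, 100), "exceeds")
})

test_that("dwc statistics summarise the channel difference per class", {
  df <- tibble::tibble(lab = c("a", "a", "b", "b"),
                       c3 = c(2, 4, 1, 1), c4 = c(1, 1, 2, 4))
  out <- dwc_stats(df, c3, c4, lab)
  expect_equal(out$mwc, c(2, -2))
  expect_equal(out$sdwc, c(1, 1))  # population SD of {1, 3}
  same <- dwc_stats(tibble::tibble(lab = c("a", "b"), v = c(1, 2)),
                    v, v, lab)
  expect_equal(same$mwc, c(0, 0))
  expect_equal(same$sdwc, c(0, 0))
})

test_that("the synthetic classes flip the sign of the mean channel gap", {
  f <- extract_features(small_trial_set(n_per_class = 6, seed = 0),
                        tau_max = 3)
  out <- dwc_stats(f, s3_C3, s3_C4, label)
  expect_equal(sort(sign(out$mwc)), c(-1, 1))
})
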