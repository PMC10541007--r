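# delta-F/F, triggered averages, permutation bands, onset extrapolation.

test_that("delta-F/F follows the 10th-percentile baseline definition", {
  # constant trace: f0 = c, dff identically 0
  tr <- compute_dff(rep(3, 1000), fs = 100, target_fs = NULL)
  expect_equal(tr$f0, 3)
  expect_equal(tr$dff, rep(0, 1000))
  # 5% of samples at 2, rest at 1: f0 = 1, peak dff = 1
  x <- rep(1, 1000); x[1:50] <- 2
  tr <- compute_dff(x, fs = 100, target_fs = NULL)
  expect_equal(tr$f0, 1)
  expect_equal(max(tr$dff), 1)
  # non-positive trace is rejected
  expect_error(compute_dff(c(rep(1, 99), -0.1), 100, target_fs = NULL),
               "positive")
})

test_that("decimation preserves slow structure and rejects non-integer ratios", {
  fs <- 5000
  t <- (0:(fs * 4 - 1)) / fs
  x <- 10 + sin(2 * pi * 0.5 * t)
  d <- decimate_trace(x, fs, 1000)
  expect_equal(d$fs, 1000)
  expect_equal(length(d$x), 4000)
  mid <- 500:3500  # away from filter edge transients
  ref <- 10 + sin(2 * pi * 0.5 * (mid - 1) / 1000)
  # the anti-alias filter applies a small constant passband gain; the
  # shape must be preserved once that gain is divided out
  g <- mean(d$x[mid] / ref)
  expect_lt(abs(g - 1), 0.02)
  expect_lt(max(abs(d$x[mid] / g - ref)), 0.02)
  expect_error(decimate_trace(x, 5000, 1100), "integer")
})

test_that("triggered average reproduces identical planted transients", {
  fs <- 100
  truth <- mk_song_truth(6, gap_s = 30)
  raw <- synth_photometry(truth, fs = fs, lead_s = 2, amp = 0.4,
                          noise_sd = 0, duration_s = 200)
  tr <- compute_dff(raw, fs, target_fs = NULL)
  avg <- triggered_average(tr, truth$songs$onset_s, pre_s = 4, post_s = 4)
  expect_equal(avg$n_events, 6L)
  # single-event segment equals the mean (all transients identical)
  one <- triggered_average(tr, truth$songs$onset_s[3], pre_s = 4, post_s = 4)
  expect_equal(one$mean, avg$mean, tolerance = 1e-10)
  # the transient rises after -2 s and peaks positive
  expect_gt(max(avg$mean), 0.05)
  expect_lt(max(abs(avg$mean[avg$t < -2.2])), 1e-8)
})

test_that("averaging n noise-only events shrinks amplitude like 1/sqrt(n)", {
  set.seed(31)
  raw <- 5 + rnorm(300 * 50, sd = 0.25)
  tr <- compute_dff(raw, 50, target_fs = NULL)
  trig <- runif(100, 10, 290)
  avg <- triggered_average(tr, trig, pre_s = 5, post_s = 5)
  ratio <- sd(avg$mean) / sd(tr$dff)
  expect_gt(ratio, 0.05); expect_lt(ratio, 0.2)
})

test_that("clipped trigger windows are dropped and counted", {
  tr <- compute_dff(rep(2, 1000), 100, target_fs = NULL)
  avg <- triggered_average(tr, c(0.5, 5, 9.9), pre_s = 2, post_s = 2)
  expect_equal(avg$n_events, 1L)
  expect_equal(avg$n_dropped, 2L)
  expect_error(triggered_average(tr, c(0.1), pre_s = 2, post_s = 2),
               "no usable triggers")
})

test_that("permutation bands are reproducible and detect planted signals", {
  fs <- 50
  truth <- mk_song_truth(10, gap_s = 25)
  raw <- synth_photometry(truth, fs = fs, lead_s = 2, amp = 0.5,
                          noise_sd = 0.03, duration_s = 270, seed = 8)
  tr <- compute_dff(raw, fs, target_fs = NULL)
  avg <- triggered_average(tr, truth$songs$onset_s, pre_s = 5, post_s = 5)
  b1 <- permutation_bands(tr, avg, n_perm = 200, seed = 123)
  b2 <- permutation_bands(tr, avg, n_perm = 200, seed = 123)
  expect_identical(b1$null_mean, b2$null_mean)
  expect_identical(b1$p_value, b2$p_value)
  expect_lte(b1$p_value, 0.05)
  expect_true(all(b1$null_sd >= 0))
})

test_that("delaying all triggers shifts the average and the onset by -delta", {
  fs <- 100
  truth <- mk_song_truth(5, gap_s = 30)
  raw <- synth_photometry(truth, fs = fs, lead_s = 2, amp = 0.5,
                          noise_sd = 0.01, duration_s = 170, seed = 4)
  tr <- compute_dff(raw, fs, target_fs = NULL)
  delta <- 0.5
  a0 <- triggered_average(tr, truth$songs$onset_s, pre_s = 5, post_s = 3)
  a1 <- triggered_average(tr, truth$songs$onset_s + delta, pre_s = 5, post_s = 3)
  k <- delta * fs
  n <- length(a0$mean)
  expect_equal(a1$mean[seq_len(n - k)], a0$mean[(k + 1):n], tolerance = 1e-10)
  o0 <- estimate_onset(a0, search_s = c(-4, 1))
  o1 <- estimate_onset(a1, search_s = c(-4, 1))
  expect_equal(as.numeric(o1), as.numeric(o0) - delta, tolerance = 0.05)
})

test_that("onset extrapolation is exact on an ideal linear rise", {
  t <- seq(-5, 5, by = 0.01)
  y <- pmin(pmax((t + 2) / 2, 0), 1)
  onset <- estimate_onset(mk_avg(t, y))
  expect_equal(as.numeric(onset), -2, tolerance = 0.011)
})

test_that("degenerate averages are rejected with informative errors", {
  t <- seq(-5, 5, by = 0.01)
  expect_error(estimate_onset(mk_avg(t, rep(0, length(t)))), "no positive peak")
  # instantaneous step: fewer than 3 samples between 10% and 90%
  y <- as.numeric(t >= 0)
  expect_error(estimate_onset(mk_avg(t, y)), "too fast")
})

test_that("the programmed calcium lead is recovered from synthetic sessions", {
  est <- sapply(1:5, function(i) {
    truth <- mk_song_truth(12, gap_s = 25)
    raw <- synth_photometry(truth, fs = 200, lead_s = 2.3, amp = 0.5,
                            noise_sd = 0.05, duration_s = 320, seed = i)
    tr <- compute_dff(raw, 200, target_fs = NULL)
    avg <- triggered_average(tr, truth$songs$onset_s, pre_s = 6, post_s = 4)
    as.numeric(estimate_onset(avg, search_s = c(-5, 2)))
  })
  expect_lt(abs(mean(est) - (-2.3)), 0.3)
})
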