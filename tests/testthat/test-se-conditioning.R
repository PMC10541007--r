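# SE outcome labelling, condition-split PETHs, delta-PETH and its null.

test_that("SEs are labelled by vocal outcome within the follow window", {
  cfg <- conditioning_config()
  se <- data.frame(onset_s = 0, offset_s = 5)
  songs <- data.frame(onset_s = 6.2)
  log1 <- label_se_outcomes(se, songs, cfg)
  expect_equal(log1$se$outcome, "Song-Inducing")
  expect_equal(log1$songs$provenance, "SE-preceded")
  # no song until 30 s -> Quiet SE, isolated song
  log2 <- label_se_outcomes(se, data.frame(onset_s = 30), cfg)
  expect_equal(log2$se$outcome, "Quiet")
  expect_equal(log2$songs$provenance, "isolated")
  # a song during the ongoing SE counts as Song-Inducing
  log3 <- label_se_outcomes(se, data.frame(onset_s = 2), cfg)
  expect_equal(log3$se$outcome, "Song-Inducing")
  expect_equal(log3$songs$provenance, "SE-preceded")
  # overlapping SEs are rejected
  expect_error(label_se_outcomes(data.frame(onset_s = c(0, 3),
                                            offset_s = c(5, 8)),
                                 songs, cfg), "overlapping")
})

test_that("songs attach to the nearest preceding qualifying SE", {
  cfg <- conditioning_config()
  se <- data.frame(se_id = c(1L, 2L), onset_s = c(0, 8), offset_s = c(5, 13))
  lg <- label_se_outcomes(se, data.frame(onset_s = 9.5), cfg)
  expect_equal(lg$songs$se_id, 2L)
  expect_equal(lg$se$outcome, c("Quiet", "Song-Inducing"))
})

test_that("isolation requires 5 s from every earlier SE offset", {
  cfg <- conditioning_config()
  se <- data.frame(onset_s = 0, offset_s = 5)
  near <- label_se_outcomes(se, data.frame(onset_s = 9.9), cfg)
  expect_equal(near$songs$provenance, "SE-preceded")
  far <- label_se_outcomes(se, data.frame(onset_s = 10.1), cfg)
  expect_equal(far$songs$provenance, "isolated")
})

test_that("low-rate units are excluded from the split analysis", {
  truth <- mk_se_truth(20, p_song = 0.5, spacing = 20, seed = 6)
  se_log <- label_se_outcomes(truth$se, truth$songs, conditioning_config())
  sp <- synth_spikes(truth, synth_units(1, class = "None", baseline_hz = 0.5),
                     420, seed = 1)
  res <- split_peth(sp$time_s, se_log, conditioning_config())
  expect_true(res$excluded)
  expect_match(res$reason, "below")
  # a healthy unit is admitted and yields both PETHs
  sp2 <- synth_spikes(truth, synth_units(1, class = "SE"), 420, seed = 2)
  res2 <- split_peth(sp2$time_s, se_log, conditioning_config())
  expect_false(res2$excluded)
  expect_s3_class(res2$peth_song_inducing, "peth")
  expect_equal(res2$n_si + res2$n_q, 20L)
})

test_that("delta-PETH is the response-window mean difference", {
  cfg <- conditioning_config()
  expect_equal(delta_peth(mk_flat_peth(5), mk_flat_peth(5), cfg), 0)
  expect_equal(delta_peth(mk_flat_peth(6), mk_flat_peth(4), cfg), 2)
  expect_error(delta_peth(mk_flat_peth(6, pre_s = 1, post_s = 1),
                          mk_flat_peth(4, pre_s = 1, post_s = 1), cfg),
               "outside")
  expect_error(delta_peth(mk_flat_peth(6), mk_flat_peth(4, bin_s = 0.5), cfg),
               "bin edges")
})

test_that("a planted outcome gain is recovered in the delta", {
  # gain 2 on a 10 Hz SE kernel: expected delta ~ amp*(g-1)*mean(K over [0,2])
  kmean <- integrate(function(t) exp(-(t - 1)^2 / (2 * 0.4^2)), 0, 2)$value / 2
  expected <- 10 * (2 - 1) * kmean
  deltas <- sapply(1:20, function(i) {
    truth <- mk_se_truth(40, p_song = 0.5, spacing = 18, seed = i)
    se_log <- label_se_outcomes(truth$se, truth$songs, conditioning_config())
    sp <- synth_spikes(truth, synth_units(1, class = "SE", amp_hz = 10,
                                          gain = 2),
                       max(truth$se$offset_s) + 15, seed = 300 + i)
    r <- shuffle_null(sp$time_s, se_log,
                      conditioning_config(n_shuffle = 200, seed = 400 + i))
    r$delta_hz
  })
  expect_lt(abs(mean(deltas) - expected), 1.2)
})

test_that("the shuffle null is centred, label-conserving and reproducible", {
  truth <- mk_se_truth(30, p_song = 0.5, spacing = 18, seed = 9)
  se_log <- label_se_outcomes(truth$se, truth$songs, conditioning_config())
  sp <- synth_spikes(truth, synth_units(1, class = "SE"),
                     max(truth$se$offset_s) + 15, seed = 10)
  cfg <- conditioning_config(n_shuffle = 500, seed = 55)
  r1 <- shuffle_null(sp$time_s, se_log, cfg)
  r2 <- shuffle_null(sp$time_s, se_log, cfg)
  expect_identical(r1$null, r2$null)
  expect_equal(length(r1$null), 500L)
  # null centring: |mean| <= 6 * SD / sqrt(n_shuffle)
  expect_lte(abs(mean(r1$null)), 6 * sd(r1$null) / sqrt(500))
  # class counts preserved: n_si + n_q equals the capped SE count
  expect_equal(r1$n_si + r1$n_q, min(30L, cfg$max_se_per_unit))
})

test_that("an empty outcome class yields Agnostic-by-default", {
  se <- data.frame(se_id = 1:4, onset_s = c(0, 20, 40, 60),
                   offset_s = c(5, 25, 45, 65))
  songs <- data.frame(onset_s = c(1, 21, 41, 61))  # every SE sings
  se_log <- label_se_outcomes(se, songs, conditioning_config())
  r <- shuffle_null(sort(runif(100, 0, 70)), se_log, conditioning_config())
  expect_true(r$undefined)
  expect_equal(r$category, "Agnostic")
})

test_that("outcome-blind units are Agnostic, gain units Song-Inducing", {
  cats_null <- sapply(1:30, function(i) {
    truth <- mk_se_truth(40, 0.5, seed = i)
    se_log <- label_se_outcomes(truth$se, truth$songs, conditioning_config())
    sp <- synth_spikes(truth, synth_units(1, class = "SE", gain = 1),
                       max(truth$se$offset_s) + 15, seed = 1000 + i)
    shuffle_null(sp$time_s, se_log,
                 conditioning_config(n_shuffle = 300, seed = 2000 + i))$category
  })
  expect_gte(mean(cats_null == "Agnostic"), 0.8)
  cats_gain <- sapply(1:15, function(i) {
    truth <- mk_se_truth(40, 0.5, seed = 100 + i)
    se_log <- label_se_outcomes(truth$se, truth$songs, conditioning_config())
    sp <- synth_spikes(truth, synth_units(1, class = "SE", amp_hz = 10,
                                          gain = 2.5),
                       max(truth$se$offset_s) + 15, seed = 3000 + i)
    shuffle_null(sp$time_s, se_log,
                 conditioning_config(n_shuffle = 300, seed = 4000 + i))$category
  })
  expect_gte(mean(cats_gain == "Song-Inducing"), 0.8)
})

test_that("population CDF shift is null-centred without gain, rightward with", {
  run_pop <- function(g, seed0) {
    truth <- mk_se_truth(40, 0.5, seed = seed0)
    se_log <- label_se_outcomes(truth$se, truth$songs, conditioning_config())
    units <- synth_units(12, class = "SE", amp_hz = 10, gain = g)
    sp <- synth_spikes(truth, units, max(truth$se$offset_s) + 15,
                       seed = seed0 + 1)
    dpa <- delta_peth_analysis(sp, se_log,
                               conditioning_config(n_shuffle = 300,
                                                   seed = seed0 + 2))
    population_cdf_shift(dpa$results)
  }
  null_pop <- run_pop(1, 81)
  expect_lt(abs(null_pop$mean_shift), 1)
  expect_gt(null_pop$p_value, 0.05)
  gain_pop <- run_pop(2.5, 91)
  expect_gt(gain_pop$mean_shift, 1)
  expect_lt(gain_pop$p_value, 0.05)
})
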