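# Spectrogram, binarization/cleaning, syllable extraction, features, songs.

make_tone <- function(freq_hz, dur_s, fs = 250000, snr_db = 40,
                      total_s = dur_s + 0.2, t0 = 0.1, seed = 1) {
  set.seed(seed)
  x <- rnorm(round(total_s * fs))
  amp <- sqrt(2 * 10^(snr_db / 10))
  i <- round(t0 * fs) + seq_len(round(dur_s * fs))
  x[i] <- x[i] + amp * sin(2 * pi * freq_hz * (seq_along(i) - 1) / fs)
  x
}

make_chirp <- function(f0, f1, dur_s, fs = 250000, snr_db = 40,
                       total_s = dur_s + 0.2, t0 = 0.1, seed = 1) {
  set.seed(seed)
  x <- rnorm(round(total_s * fs))
  amp <- sqrt(2 * 10^(snr_db / 10))
  tt <- (seq_len(round(dur_s * fs)) - 1) / fs
  finst <- f0 + (f1 - f0) * tt / dur_s
  i <- round(t0 * fs) + seq_along(tt)
  x[i] <- x[i] + amp * sin(2 * pi * cumsum(finst) / fs)
  x
}

test_that("a pure tone concentrates power at its frequency", {
  spec <- compute_spectrogram(make_tone(70000, 0.05), 250000)
  peak_rows <- apply(spec$power[, spec$t > 0.11 & spec$t < 0.14], 2, which.max)
  expect_true(all(abs(spec$f[peak_rows] - 70000) <= spec$df))
})

test_that("silence yields near-zero power and too-low fs errors", {
  x <- rep(0, 250000 %/% 4)
  spec <- compute_spectrogram(x, 250000)
  expect_true(all(spec$power < 1e-20))
  expect_error(compute_spectrogram(rnorm(10000), 100000), "cannot represent")
})

test_that("a chirp's spectrogram ridge spans the programmed sweep", {
  spec <- compute_spectrogram(make_chirp(60000, 80000, 0.02), 250000)
  mid <- spec$t > 0.1 & spec$t < 0.12
  peak_rows <- apply(spec$power[, mid], 2, which.max)
  expect_lt(abs(min(spec$f[peak_rows]) - 60000), 3 * spec$df)
  expect_lt(abs(max(spec$f[peak_rows]) - 80000), 3 * spec$df)
})

test_that("isolated pixels are removed, supported pixels survive", {
  set.seed(4)
  # noise floor whose log-power is standard normal per pixel
  pw <- matrix(exp(rnorm(31 * 41)), 31, 41)
  hot <- exp(50)
  pw[5, 5] <- hot                      # fully isolated
  pw[10:12, 10:12] <- hot              # 3x3 block
  pw[20, 20] <- hot; pw[21, 21] <- hot # diagonal-adjacent pair
  spec <- structure(list(power = pw, t = (1:41) * 1e-3, f = (1:31) * 500,
                         dt = 1e-3, df = 500), class = "usv_spectrogram")
  mask <- binarize_and_clean(spec, seg_config())
  expect_false(mask[5, 5])
  expect_true(all(mask[10:12, 10:12]))
  expect_true(mask[20, 20] && mask[21, 21])
})

test_that("raising the detection threshold never adds pixels", {
  set.seed(9)
  pw <- matrix(exp(rnorm(40 * 200, sd = 2)), 40, 200)
  spec <- structure(list(power = pw, t = (1:200) * 1e-3, f = (1:40) * 500,
                         dt = 1e-3, df = 500), class = "usv_spectrogram")
  n_detected <- sapply(c(2, 3, 4, 5), function(z) {
    sum(binarize_and_clean(spec, seg_config(detect_z = z)))
  })
  expect_true(all(diff(n_detected) <= 0))
})

test_that("duration and gap rules apply inclusively on the bin grid", {
  cfg <- seg_config()
  # 16 bins of 0.5 ms = 8 ms -> retained; 14 bins = 7 ms -> rejected
  m <- mk_mask(100, list(c(21, 36)))
  expect_equal(nrow(extract_syllables(m$mask, m$times, cfg)), 1L)
  syl <- extract_syllables(m$mask, m$times, cfg)
  expect_equal(syl$duration_ms, 8, tolerance = 1e-9)
  m <- mk_mask(100, list(c(21, 34)))
  expect_equal(nrow(extract_syllables(m$mask, m$times, cfg)), 0L)
  # two 10 ms runs, 10 ms apart -> one ~30 ms syllable
  m <- mk_mask(200, list(c(21, 40), c(61, 80)))
  syl <- extract_syllables(m$mask, m$times, cfg)
  expect_equal(nrow(syl), 1L)
  expect_equal(syl$duration_ms, 30, tolerance = 1e-9)
  # two 10 ms runs, exactly 16 ms apart -> two syllables
  m <- mk_mask(200, list(c(21, 40), c(73, 92)))
  expect_equal(nrow(extract_syllables(m$mask, m$times, cfg)), 2L)
  # empty mask -> empty list
  m <- mk_mask(50, list())
  expect_equal(nrow(extract_syllables(m$mask, m$times, cfg)), 0L)
})

test_that("raising the minimum duration never adds syllables", {
  set.seed(21)
  m <- mk_mask(2000, lapply(seq(1, 1900, by = 95),
                            function(i) c(i, i + sample(5:60, 1))))
  counts <- sapply(c(4, 8, 16, 30), function(ms) {
    nrow(extract_syllables(m$mask, m$times, seg_config(min_syllable_ms = ms)))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("features recover carrier, sweep and duration of programmed sounds", {
  # constant 70 kHz tone, 25 ms
  x <- make_tone(70000, 0.025)
  seg <- segment_usv(x, 250000)
  expect_equal(nrow(seg$syllables), 1L)
  expect_lt(abs(seg$syllables$mean_freq_hz - 70000), 1000)
  expect_lte(seg$syllables$bandwidth_hz, 2 * 250000 / 512)
  expect_lt(abs(seg$syllables$duration_ms - 25), 2.1)
  # linear chirp 60 -> 80 kHz; the sweep traverses ~2 kHz within a single
  # 512-sample analysis window, so the bandwidth estimate is only defined
  # up to that smear plus the mainlobe width
  xc <- make_chirp(60000, 80000, 0.02)
  segc <- segment_usv(xc, 250000)
  expect_equal(nrow(segc$syllables), 1L)
  expect_lt(abs(segc$syllables$mean_freq_hz - 70000), 1500)
  smear <- 20000 * 512 / (0.02 * 250000) + 2 * 250000 / 512
  expect_lt(abs(segc$syllables$bandwidth_hz - 20000), smear)
})

test_that("song grouping splits at (inclusive) 10 s of silence", {
  cfg <- seg_config()
  syl <- data.frame(start_s = c(0, 0.2, 0.4), end_s = c(0.1, 0.3, 0.5))
  expect_equal(nrow(group_songs(syl, cfg)$songs), 1L)
  syl2 <- data.frame(start_s = c(0, 0.2, 12.3, 12.5),
                     end_s = c(0.1, 0.3, 12.4, 12.6))
  expect_equal(nrow(group_songs(syl2, cfg)$songs), 2L)
  # exactly 10 s from last offset to next onset -> two songs
  syl3 <- data.frame(start_s = c(0, 10.1), end_s = c(0.1, 10.2))
  expect_equal(nrow(group_songs(syl3, cfg)$songs), 2L)
  # gap below 10 s (9.9 s from offset to onset) keeps one song
  syl4 <- data.frame(start_s = c(0, 10.0), end_s = c(0.1, 10.1))
  expect_equal(nrow(group_songs(syl4, cfg)$songs), 1L)
})

test_that("segmentation recovers the planted session nearly perfectly", {
  ses <- segmented_session()
  tr <- ses$truth$syllables
  det <- ses$seg$syllables
  # recall: planted syllables found with <= 2 ms boundary error
  on_err <- sapply(tr$start_s, function(s) min(abs(det$start_s - s)))
  off_err <- sapply(tr$end_s, function(s) min(abs(det$end_s - s)))
  expect_gte(mean(on_err <= 0.002 & off_err <= 0.002), 0.95)
  # precision: every detection corresponds to a planted syllable
  fp <- sapply(det$start_s, function(s) min(abs(tr$start_s - s)))
  expect_gte(mean(fp <= 0.002), 0.95)
  # features match programme
  m <- sapply(tr$start_s, function(s) which.min(abs(det$start_s - s)))
  expect_lt(max(abs(det$mean_freq_hz[m] - tr$carrier_hz)), 1000)
  expect_lt(max(abs(det$bandwidth_hz[m] - tr$bandwidth_hz)), 2 * 250000 / 512)
  # song structure is reproduced
  expect_equal(nrow(ses$seg$songs), nrow(ses$truth$songs))
  expect_equal(ses$seg$songs$onset_s, ses$truth$songs$onset_s,
               tolerance = 0.003)
  # partition property: songs' syllables reproduce the syllable list
  expect_equal(unlist(lapply(split(det, det$song_id), function(d) d$start_s),
                      use.names = FALSE),
               det$start_s)
})
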