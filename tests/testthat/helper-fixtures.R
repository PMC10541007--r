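# Shared fixture builders. Everything is generated in code; no stored data.

# ground-truth song table only (for photometry tests that need no audio)
mk_song_truth <- function(n_songs, gap_s = 25, t0 = 15) {
  list(songs = data.frame(song_id = seq_len(n_songs),
                          onset_s = t0 + (seq_len(n_songs) - 1) * gap_s))
}

# SE session ground truth with outcomes but no audio: n_se SEs of 5 s,
# spaced `spacing` s; a song at latency 1.2 s follows each "song" SE
mk_se_truth <- function(n_se, p_song = 0.5, spacing = 18, seed = 1) {
  set.seed(seed)
  on <- 15 + (seq_len(n_se) - 1) * spacing
  out <- ifelse(runif(n_se) < p_song, "song", "quiet")
  if (all(out == "song")) out[1] <- "quiet"
  if (all(out == "quiet")) out[1] <- "song"
  songs <- data.frame(song_id = seq_len(sum(out == "song")),
                      onset_s = on[out == "song"] + 1.2)
  list(se = data.frame(se_id = seq_len(n_se), onset_s = on,
                       offset_s = on + 5, outcome = out),
       songs = songs)
}

# detection mask + time axis with exact bin widths (for boundary tests)
mk_mask <- function(n_bins, on_runs, dt = 5e-4, n_rows = 5L) {
  mask <- matrix(FALSE, n_rows, n_bins)
  for (r in on_runs) mask[, r[1]:r[2]] <- TRUE
  list(mask = mask, times = (seq_len(n_bins) - 0.5) * dt, dt = dt)
}

# hand-built peth object with a flat rate (delta-PETH arithmetic tests)
mk_flat_peth <- function(rate_hz, pre_s = 5, post_s = 5, bin_s = 0.25) {
  edges <- seq(-pre_s, post_s, by = bin_s)
  structure(list(edges = edges, mid = edges[-length(edges)] + bin_s / 2,
                 rate = rep(rate_hz, length(edges) - 1L),
                 n_trials = 10L, bin_s = bin_s,
                 pre_s = pre_s, post_s = post_s),
            class = "peth")
}

# hand-built triggered average (onset-fit geometry tests)
mk_avg <- function(t, y) {
  structure(list(t = t, mean = y, n_events = 1L, fs = 1 / (t[2] - t[1])),
            class = "triggered_average")
}

# one segmented synthetic session, shared by the recovery tests (built
# once per test run; ~100 s of 250 kHz audio)
segmented_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(duration_s = 110, n_se = 5, p_song_given_se = 1,
                          syllables_per_song = c(10L, 10L), snr_db = 20,
                          seed = 42)
      ses <- synth_usv_audio(cfg)
      cache <<- list(cfg = cfg, truth = ses$truth, fs = ses$fs,
                     seg = segment_usv(ses$waveform, ses$fs))
    }
    cache
  }
})
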