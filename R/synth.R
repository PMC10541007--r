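# Synthetic courtship sessions with known ground truth.
#
# The generator emulates the statistical structure the downstream analyses
# assume: frequency-modulated ultrasonic syllables grouped into songs
# separated by >= 10 s, social exposures (SEs) that elicit songs with
# probability ~0.65 at ~1-2 s latency, Ca2+ transients whose onsets lead
# song onsets by a configurable lag, and Poisson spike trains with SE- and
# song-locked rate modulations (with a multiplicative gain on Song-Inducing
# trials). Every output comes with the ground-truth tables that produced it.

#' Synthetic-session configuration
#'
#' @param duration_s session length, seconds.
#' @param audio_fs audio sampling rate, Hz (ultrasonic recordings are
#'   digitized at 250 kHz).
#' @param n_se number of social exposures (female presentations).
#' @param se_duration_s SE length, seconds; presentations are kept short
#'   and never exceed 10 s.
#' @param se_min_spacing_s minimum SE onset-to-onset spacing, seconds.
#'   The default (20 s) leaves room for the 10 s inter-song silence and the
#'   5 s isolation rule even with the slowest song latencies.
#' @param p_song_given_se probability an SE elicits a song (~0.65 of
#'   female presentations result in songs).
#' @param song_latency_s range (min, max) of SE-onset-to-song-onset
#'   latency, seconds; latencies are drawn log-normally with a ~1-2 s mode
#'   and truncated to this range.
#' @param n_spont_songs number of spontaneous (isolated) songs to place in
#'   SE-free stretches of the session.
#' @param syllables_per_song integer range (min, max) of syllables per song.
#' @param syllable_dur_ms syllable duration range, ms.
#' @param syllable_gap_ms inter-syllable gap range, ms (must respect the
#'   16 ms silence rule).
#' @param carrier_khz mean and SD of the syllable carrier frequency, kHz
#'   (courtship syllables sit around ~60-110 kHz).
#' @param bandwidth_khz frequency-modulation bandwidth (total sweep), kHz.
#' @param snr_db audio signal-to-noise ratio: tone power over broadband
#'   white-noise power, dB.
#' @param seed RNG seed; identical config + seed reproduces the session
#'   exactly.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 120, audio_fs = 250000,
                         n_se = 4, se_duration_s = 5,
                         se_min_spacing_s = 20,
                         p_song_given_se = 0.65,
                         song_latency_s = c(0.5, 3),
                         n_spont_songs = 0,
                         syllables_per_song = c(4L, 10L),
                         syllable_dur_ms = c(15, 50),
                         syllable_gap_ms = c(40, 120),
                         carrier_khz = c(mean = 77.5, sd = 8),
                         bandwidth_khz = 12,
                         snr_db = 20,
                         seed = 1L) {
  stopifnot_scalar_num(duration_s, "duration_s", lo = 1)
  stopifnot_scalar_num(p_song_given_se, "p_song_given_se", lo = 0, hi = 1)
  if (se_duration_s > 10) stop("se_duration_s must be <= 10 s")
  if (syllable_gap_ms[1] < 16)
    stop("inter-syllable gaps below 16 ms would merge under the parsing rules")
  if (se_min_spacing_s < 15) stop("se_min_spacing_s must be >= 15 s")
  structure(list(duration_s = duration_s, audio_fs = audio_fs,
                 n_se = as.integer(n_se), se_duration_s = se_duration_s,
                 se_min_spacing_s = se_min_spacing_s,
                 p_song_given_se = p_song_given_se,
                 song_latency_s = song_latency_s,
                 n_spont_songs = as.integer(n_spont_songs),
                 syllables_per_song = as.integer(syllables_per_song),
                 syllable_dur_ms = syllable_dur_ms,
                 syllable_gap_ms = syllable_gap_ms,
                 carrier_khz = carrier_khz, bandwidth_khz = bandwidth_khz,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "synth_config")
}

# sorted event onsets in [lo, hi] with pairwise spacing >= gap
draw_spaced_onsets <- function(n, lo, hi, gap) {
  if (n == 0L) return(numeric(0))
  slack <- (hi - lo) - (n - 1) * gap
  if (slack < 0) stop("cannot fit ", n, " events with spacing ", gap,
                      " s in [", lo, ", ", hi, "] s")
  sort(runif(n, 0, slack)) + lo + (seq_len(n) - 1) * gap
}

# ground-truth schedule: SE intervals, song onsets, per-song syllables
synth_schedule <- function(cfg) {
  lat_med <- 1.5
  max_song_dur <- cfg$syllables_per_song[2] *
    (cfg$syllable_dur_ms[2] + cfg$syllable_gap_ms[2]) / 1000
  margin <- cfg$se_duration_s + cfg$song_latency_s[2] + max_song_dur + 1
  se_on <- draw_spaced_onsets(cfg$n_se, 2, cfg$duration_s - margin,
                              cfg$se_min_spacing_s)
  se <- data.frame(se_id = seq_len(cfg$n_se),
                   onset_s = se_on,
                   offset_s = se_on + cfg$se_duration_s)
  sings <- if (cfg$n_se > 0) rbinom(cfg$n_se, 1L, cfg$p_song_given_se) == 1L
           else logical(0)
  lat <- pmin(pmax(rlnorm(cfg$n_se, log(lat_med), 0.4),
                   cfg$song_latency_s[1]), cfg$song_latency_s[2])
  song_on <- se_on[sings] + lat[sings]
  song_se <- se$se_id[sings]
  if (cfg$n_spont_songs > 0L) {
    # place isolated songs in stretches >= song-gap away from SEs and songs
    lo <- 12; hi <- cfg$duration_s - max_song_dur - 12
    cand <- draw_spaced_onsets(cfg$n_spont_songs * 8L, lo, hi, 1)
    busy <- c(se$onset_s, song_on)
    ok <- vapply(cand, function(t0) {
      all(abs(t0 - busy) > 12 + max_song_dur) &&
        all(t0 < se$onset_s | t0 > se$offset_s + 12)
    }, logical(1))
    picked <- head(cand[ok], cfg$n_spont_songs)
    if (length(picked) < cfg$n_spont_songs)
      stop("could not place ", cfg$n_spont_songs, " isolated songs; ",
           "increase duration_s")
    song_on <- c(song_on, picked)
    song_se <- c(song_se, rep(NA_integer_, length(picked)))
  }
  ord <- order(song_on)
  song_on <- song_on[ord]; song_se <- song_se[ord]

  syl <- vector("list", length(song_on))
  songs <- data.frame(song_id = seq_along(song_on), onset_s = song_on,
                      offset_s = song_on, se_id = song_se,
                      n_syllables = integer(length(song_on)))
  for (k in seq_along(song_on)) {
    ns_range <- cfg$syllables_per_song[1]:cfg$syllables_per_song[2]
    ns <- ns_range[sample.int(length(ns_range), 1L)]
    dur <- runif(ns, cfg$syllable_dur_ms[1], cfg$syllable_dur_ms[2]) / 1000
    gap <- runif(ns, cfg$syllable_gap_ms[1], cfg$syllable_gap_ms[2]) / 1000
    st <- song_on[k] + cumsum(c(0, (dur + gap)[-ns]))
    carrier <- rnorm(ns, cfg$carrier_khz[["mean"]], cfg$carrier_khz[["sd"]]) * 1000
    carrier <- pmin(pmax(carrier, 40000), 115000)
    syl[[k]] <- data.frame(song_id = k, start_s = st, end_s = st + dur,
                           carrier_hz = carrier,
                           bandwidth_hz = rep(cfg$bandwidth_khz * 1000, ns))
    songs$offset_s[k] <- st[ns] + dur[ns]
    songs$n_syllables[k] <- ns
  }
  syllables <- if (length(syl)) do.call(rbind, syl) else
    data.frame(song_id = integer(0), start_s = numeric(0),
               end_s = numeric(0), carrier_hz = numeric(0),
               bandwidth_hz = numeric(0))
  # invariant: consecutive songs separated by >= 10 s of silence
  if (nrow(songs) > 1L) {
    g <- songs$onset_s[-1L] - songs$offset_s[-nrow(songs)]
    if (any(g < 10)) stop("generated songs violate the 10 s inter-song gap; ",
                          "increase se_min_spacing_s or duration_s")
  }
  list(se = se, songs = songs, syllables = syllables)
}

#' Synthesize a USV audio session with ground truth
#'
#' Each syllable is a sinusoid-FM tone burst: the instantaneous frequency
#' sweeps the programmed bandwidth around the carrier sinusoidally over the
#' syllable, with 1 ms raised-cosine on/off ramps. Broadband white Gaussian
#' noise is added at the configured SNR. Ground-truth tables list every
#' syllable interval (half-open, seconds), song, and SE with its vocal
#' outcome.
#'
#' @param cfg a [synth_config()].
#' @return list with `waveform`, `fs`, and `truth` (list of data.frames:
#'   `syllables`, `songs`, `se`).
#' @export
synth_usv_audio <- function(cfg = synth_config()) {
  with_seed(cfg$seed, {
    sch <- synth_schedule(cfg)
    fs <- cfg$audio_fs
    n <- round(cfg$duration_s * fs)
    noise_sd <- 1
    amp <- sqrt(2 * noise_sd^2 * 10^(cfg$snr_db / 10))
    x <- rnorm(n, sd = noise_sd)
    if (nrow(sch$syllables) > 0L) {
      for (i in seq_len(nrow(sch$syllables))) {
        s <- sch$syllables[i, ]
        i0 <- floor(s$start_s * fs) + 1L
        i1 <- min(ceiling(s$end_s * fs), n)
        tt <- (seq(i0, i1) - i0) / fs
        d <- s$end_s - s$start_s
        # one full FM cycle starting and ending at the carrier, with the
        # band extremes reached in the syllable interior
        finst <- s$carrier_hz +
          (s$bandwidth_hz / 2) * sin(2 * pi * tt / d)
        phase <- 2 * pi * cumsum(finst) / fs
        ramp_n <- min(round(0.001 * fs), floor(length(tt) / 2))
        env <- rep(1, length(tt))
        if (ramp_n > 0) {
          r <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
          env[seq_len(ramp_n)] <- r
          env[length(env) - ramp_n + seq_len(ramp_n)] <- rev(r)
        }
        x[i0:i1] <- x[i0:i1] + amp * env * sin(phase)
      }
    }
    se <- sch$se
    if (nrow(se) > 0L) {
      follow <- vapply(seq_len(nrow(se)), function(k)
        any(!is.na(sch$songs$se_id) & sch$songs$se_id == se$se_id[k]),
        logical(1))
      se$outcome <- ifelse(follow, "song", "quiet")
    } else se$outcome <- character(0)
    list(waveform = x, fs = fs,
         truth = list(syllables = sch$syllables, songs = sch$songs, se = se))
  })
}

#' Synthesize a fiber-photometry trace tied to ground-truth songs
#'
#' Raw fluorescence = positive baseline + one double-exponential Ca2+
#' transient per song, each with onset `lead_s` seconds *before* the song
#' onset (population activity precedes vocal initiation), + Gaussian noise
#' + optional linear drift. The kernel `(1 - exp(-t/tau_rise)) *
#' exp(-t/tau_decay)` is normalised to unit peak so `amp` is the peak
#' fluorescence deflection in raw units.
#'
#' @param truth ground truth from [synth_usv_audio()] (only `songs$onset_s`
#'   is used).
#' @param fs trace sampling rate, Hz.
#' @param lead_s transient-onset lead relative to song onset, seconds.
#' @param amp transient peak amplitude, raw fluorescence units.
#' @param tau_rise,tau_decay kernel time constants, seconds.
#' @param baseline_f baseline fluorescence (must be positive).
#' @param noise_sd Gaussian noise SD, raw units.
#' @param drift_per_s linear drift slope, raw units per second.
#' @param duration_s trace length, seconds (defaults to covering the last
#'   song plus 20 s).
#' @param seed RNG seed.
#' @return numeric raw fluorescence trace sampled at `fs`.
#' @export
synth_photometry <- function(truth, fs = 1000, lead_s = 2.3, amp = 0.5,
                             tau_rise = 0.2, tau_decay = 1.5,
                             baseline_f = 5, noise_sd = 0.02,
                             drift_per_s = 0, duration_s = NULL,
                             seed = 1L) {
  if (tau_rise <= 0 || tau_decay <= 0) stop("kernel taus must be positive")
  if (fs <= 0) stop("fs must be positive")
  if (baseline_f <= 0) stop("baseline_f must be positive")
  onsets <- truth$songs$onset_s - lead_s
  if (any(onsets < 0)) {
    warning("transient onsets before t = 0 clipped to 0")
    onsets <- pmax(onsets, 0)
  }
  if (is.null(duration_s)) {
    duration_s <- if (length(onsets)) max(truth$songs$onset_s) + 20 else 60
  }
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    f <- baseline_f + drift_per_s * tt + rnorm(n, sd = noise_sd)
    if (amp != 0 && length(onsets)) {
      tpk <- tau_rise * log(1 + tau_decay / tau_rise)
      peak <- (1 - exp(-tpk / tau_rise)) * exp(-tpk / tau_decay)
      span <- ceiling((tau_decay * 8 + tau_rise) * fs)
      kt <- (seq_len(span) - 1) / fs
      kern <- amp * (1 - exp(-kt / tau_rise)) * exp(-kt / tau_decay) / peak
      for (o in onsets) {
        i0 <- floor(o * fs) + 1L
        i1 <- min(i0 + span - 1L, n)
        if (i0 <= n) f[i0:i1] <- f[i0:i1] + kern[seq_len(i1 - i0 + 1L)]
      }
    }
    f
  })
}

#' Define a population of synthetic units
#'
#' @param n_units number of units.
#' @param class tuning class for every unit (recycled): `"SE"`, `"Song"`,
#'   `"Both"` or `"None"`.
#' @param baseline_hz,amp_hz baseline rate and event-kernel peak amplitude,
#'   Hz (recycled).
#' @param gain multiplicative gain applied to the SE response on
#'   Song-Inducing trials (recycled); `gain = 1` means the unit is blind to
#'   the vocal outcome.
#' @return data.frame usable as the `units` argument of [synth_spikes()].
#' @export
synth_units <- function(n_units, class = "SE", baseline_hz = 5,
                        amp_hz = 10, gain = 1) {
  data.frame(unit_id = seq_len(n_units),
             class = rep_len(class, n_units),
             baseline_hz = rep_len(baseline_hz, n_units),
             amp_hz = rep_len(amp_hz, n_units),
             gain = rep_len(gain, n_units))
}

# Gaussian event kernels, unit peak. The SE kernel peaks ~1 s after SE
# onset (the population response is centred around 1 s after exposure);
# the song kernel peaks before song onset (activity precedes initiation).
kernel_se <- function(t) exp(-(t - 1)^2 / (2 * 0.4^2))
kernel_song <- function(t) exp(-(t + 0.8)^2 / (2 * 0.5^2))

# evaluate a unit's rate at times tt (seconds)
unit_rate <- function(tt, unit, se, songs) {
  r <- rep(unit$baseline_hz, length(tt))
  if (unit$class %in% c("SE", "Both") && nrow(se) > 0L) {
    g <- ifelse(se$outcome == "song", unit$gain, 1)
    for (k in seq_len(nrow(se))) {
      r <- r + unit$amp_hz * g[k] * kernel_se(tt - se$onset_s[k])
    }
  }
  if (unit$class %in% c("Song", "Both") && nrow(songs) > 0L) {
    for (k in seq_len(nrow(songs))) {
      r <- r + unit$amp_hz * kernel_song(tt - songs$onset_s[k])
    }
  }
  r
}

#' Synthesize spike trains for a population of tuned units
#'
#' Each unit fires as an inhomogeneous Poisson process (simulated by
#' thinning) with rate `baseline + amp * gain^\[Song-Inducing\] * K_SE(t)`
#' for SE-tuned units and `baseline + amp * K_song(t)` for song-tuned
#' units (`Both` gets both terms, `None` is baseline only). `K_SE` peaks
#' ~1 s after SE onset; `K_song` peaks ~0.8 s before song onset.
#'
#' @param truth ground truth from [synth_usv_audio()] (uses `se` with
#'   outcomes and `songs`).
#' @param units data.frame from [synth_units()].
#' @param duration_s simulated span, seconds.
#' @param seed RNG seed.
#' @return data.frame of spikes (`unit_id`, `time_s`), sorted within unit.
#' @export
synth_spikes <- function(truth, units, duration_s, seed = 1L) {
  if (any(units$baseline_hz < 0) || any(units$amp_hz < 0))
    stop("baseline_hz and amp_hz must be non-negative")
  se <- truth$se; songs <- truth$songs
  with_seed(seed, {
    out <- vector("list", nrow(units))
    for (i in seq_len(nrow(units))) {
      u <- units[i, ]
      rmax <- u$baseline_hz +
        u$amp_hz * max(u$gain, 1) * (u$class %in% c("SE", "Both")) +
        u$amp_hz * (u$class %in% c("Song", "Both"))
      if (rmax <= 0) { out[[i]] <- numeric(0); next }
      n_cand <- rpois(1L, rmax * duration_s)
      cand <- sort(runif(n_cand, 0, duration_s))
      keep <- runif(n_cand) < unit_rate(cand, u, se, songs) / rmax
      out[[i]] <- cand[keep]
    }
    data.frame(
      unit_id = rep(units$unit_id, lengths(out)),
      time_s = unlist(out))
  })
}

#' Synthesize multi-channel raw voltage around known spike times
#'
#' Builds a channels x samples matrix: per-channel Gaussian noise (unit
#' SD), a biphasic spike template at each planted spike time on its
#' channel, and an optional common-mode signal added identically to every
#' channel. Used to exercise common-median referencing and threshold
#' detection with exact ground truth.
#'
#' @param spike_times list of numeric vectors, one per channel, seconds.
#' @param n_channels number of channels (>= length of `spike_times`).
#' @param duration_s record length, seconds.
#' @param fs sampling rate, Hz.
#' @param spike_amp_sd template peak amplitude in noise-SD units.
#' @param common_mode optional function of a time vector returning the
#'   shared signal (e.g. a mains sinusoid), or `NULL`.
#' @param seed RNG seed.
#' @return numeric matrix, channels x samples.
#' @export
synth_raw_voltage <- function(spike_times, n_channels, duration_s,
                              fs = 30000, spike_amp_sd = 12,
                              common_mode = NULL, seed = 1L) {
  n <- round(duration_s * fs)
  with_seed(seed, {
    x <- matrix(rnorm(n_channels * n), nrow = n_channels)
    # biphasic template, ~1 ms total: dominant negative deflection at
    # ~0.25 ms with a smaller positive rebound, as in extracellular
    # waveforms (the extremum defines the spike time)
    tpl_t <- seq(0, 0.001, by = 1 / fs)
    tpl <- -exp(-((tpl_t - 0.00025) / 8e-5)^2) +
      0.35 * exp(-((tpl_t - 0.0006) / 1.5e-4)^2)
    tpl <- tpl / max(abs(tpl)) * spike_amp_sd
    for (ch in seq_along(spike_times)) {
      for (ts in spike_times[[ch]]) {
        i0 <- round(ts * fs) + 1L
        idx <- i0:min(i0 + length(tpl) - 1L, n)
        x[ch, idx] <- x[ch, idx] + tpl[seq_along(idx)]
      }
    }
    if (!is.null(common_mode)) {
      cm <- common_mode((seq_len(n) - 1) / fs)
      x <- x + matrix(cm, nrow = n_channels, ncol = n, byrow = TRUE)
    }
    x
  })
}
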