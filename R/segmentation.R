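#' Segmentation configuration
#'
#' Parameters for parsing USV syllables and songs from ultrasonic audio.
#' The defaults encode the standard mouse-USV parsing rules: the spectrogram
#' is restricted to 20-125 kHz, detected pixels are cleaned with a 3x3
#' neighbourhood ("square size 3"), a syllable is a continuous frequency
#' modulation of at least 8 ms flanked by at least 16 ms of silence, and a
#' song is a run of syllables flanked by at least 10 s of quiet.
#'
#' @param f_lo,f_hi frequency band of interest, Hz.
#' @param square_size odd side length (pixels) of the cleaning window.
#' @param min_neighbors minimum number of *other* detected pixels required
#'   inside the cleaning window for a detected pixel to survive; 1 means a
#'   fully isolated pixel is removed.
#' @param detect_z robust z threshold (per-frequency-row median/MAD of
#'   log-power) for pixel detection.
#' @param feature_z second, higher threshold used only when extracting
#'   per-syllable features; must exceed `detect_z`.
#' @param leakage_db when extracting features, pixels more than this many
#'   dB below the loudest pixel of the syllable's own slab are discarded
#'   as window leakage: a louder syllable pushes more of its Hann
#'   mainlobe skirt above any noise-relative threshold, so a peak-relative
#'   floor is what keeps measured bandwidth independent of loudness. The
#'   default sits above within-ridge power fluctuation but below the
#'   attenuation of skirt bins one bin off the ridge (>= 6 dB), localizing
#'   each band edge to about one frequency bin.
#' @param min_syllable_ms minimum syllable duration, ms (inclusive).
#' @param min_gap_ms silent gap below which neighbouring detections merge
#'   into one syllable, ms; a gap `>= min_gap_ms` separates syllables.
#' @param song_gap_s silent period that separates songs, seconds
#'   (inclusive: a gap of exactly `song_gap_s` starts a new song).
#' @param stft_window,stft_hop STFT window and hop, samples. At 250 kHz the
#'   defaults give ~2 ms frequency frames every ~0.5 ms, resolving the
#'   8/16 ms duration rules with an order-of-magnitude margin.
#' @return a list of class `seg_config`.
#' @export
seg_config <- function(f_lo = 20000, f_hi = 125000,
                       square_size = 3L, min_neighbors = 1L,
                       detect_z = 4, feature_z = 6, leakage_db = 8,
                       min_syllable_ms = 8, min_gap_ms = 16,
                       song_gap_s = 10,
                       stft_window = 512L, stft_hop = 128L) {
  if (f_lo >= f_hi) stop("f_lo must be < f_hi")
  if (square_size %% 2L != 1L || square_size < 1L)
    stop("square_size must be a positive odd integer")
  if (min_syllable_ms <= 0 || min_gap_ms <= 0)
    stop("min_syllable_ms and min_gap_ms must be positive")
  if (song_gap_s <= min_gap_ms / 1000)
    stop("song_gap_s must exceed min_gap_ms/1000")
  if (feature_z < detect_z)
    stop("feature_z must be >= detect_z")
  structure(list(f_lo = f_lo, f_hi = f_hi,
                 square_size = as.integer(square_size),
                 min_neighbors = as.integer(min_neighbors),
                 detect_z = detect_z, feature_z = feature_z,
                 leakage_db = leakage_db,
                 min_syllable_ms = min_syllable_ms, min_gap_ms = min_gap_ms,
                 song_gap_s = song_gap_s,
                 stft_window = as.integer(stft_window),
                 stft_hop = as.integer(stft_hop)),
            class = "seg_config")
}

#' Band-restricted power spectrogram
#'
#' Magnitude-squared short-time Fourier transform (Hann window), restricted
#' to `[f_lo, f_hi]`. Frames are computed in chunks so that a full-length
#' 250 kHz session never materialises the out-of-band rows.
#'
#' @param waveform numeric vector of audio samples.
#' @param fs sampling rate, Hz; must be at least `2 * f_hi`.
#' @param cfg a [seg_config()].
#' @return list of class `usv_spectrogram` with `power` (freq rows x time
#'   columns), `t` (frame-centre times, seconds), `f` (row frequencies, Hz),
#'   `dt` (frame spacing, s) and `df` (row spacing, Hz).
#' @export
compute_spectrogram <- function(waveform, fs, cfg = seg_config()) {
  if (fs < 2 * cfg$f_hi) {
    stop(sprintf("fs = %g Hz cannot represent f_hi = %g Hz (need fs >= %g)",
                 fs, cfg$f_hi, 2 * cfg$f_hi))
  }
  win <- cfg$stft_window; hop <- cfg$stft_hop
  n <- length(waveform)
  if (n < win) stop("waveform shorter than one STFT window")
  w <- as.numeric(signal::hanning(win))
  freq <- (seq_len(win %/% 2 + 1L) - 1L) * fs / win
  keep <- which(freq >= cfg$f_lo & freq <= cfg$f_hi)
  if (length(keep) == 0L) stop("no frequency bins inside [f_lo, f_hi]")
  starts <- seq(1L, n - win + 1L, by = hop)
  nf <- length(starts)
  power <- matrix(0, nrow = length(keep), ncol = nf)
  chunk <- 4096L
  off <- 0:(win - 1L)
  for (i0 in seq(1L, nf, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nf)
    idx <- outer(off, starts[i0:i1], `+`)
    fr <- matrix(waveform[idx], nrow = win) * w
    sp <- stats::mvfft(fr)[keep, , drop = FALSE]
    power[, i0:i1] <- Mod(sp)^2
  }
  structure(list(power = power,
                 t = (starts - 1 + win / 2) / fs,
                 f = freq[keep],
                 dt = hop / fs,
                 df = fs / win),
            class = "usv_spectrogram")
}

# per-row robust location/scale of log-power; shared by detection and
# feature extraction so both thresholds live on the same scale
spectrogram_row_stats <- function(spec) {
  lp <- log(spec$power + .Machine$double.xmin)
  med <- apply(lp, 1L, stats::median)
  s <- apply(lp, 1L, stats::mad)
  s[s <= 0] <- stats::median(s[s > 0])
  list(logp = lp, med = med, mad = s)
}

#' Binarize a spectrogram and remove isolated pixels
#'
#' A pixel is detected when its log-power exceeds the per-frequency-row
#' robust baseline (median + `detect_z` * scaled MAD); row-wise statistics
#' make steady narrowband noise invisible to the detector. A detected pixel
#' is then removed if fewer than `min_neighbors` other detected pixels lie
#' in the `square_size` x `square_size` window centred on it, so fully
#' isolated pixels disappear.
#'
#' @param spec a [compute_spectrogram()] result.
#' @param cfg a [seg_config()].
#' @param row_stats optional precomputed per-row statistics (internal
#'   reuse by [segment_usv()]).
#' @return logical matrix of the same shape as `spec$power`.
#' @export
binarize_and_clean <- function(spec, cfg = seg_config(), row_stats = NULL) {
  if (length(spec$power) == 0L) stop("empty spectrogram")
  rs <- if (is.null(row_stats)) spectrogram_row_stats(spec) else row_stats
  z <- (rs$logp - rs$med) / rs$mad
  detected <- z >= cfg$detect_z
  nb <- box_sum(detected, cfg$square_size) - detected
  detected & (nb >= cfg$min_neighbors)
}

#' Extract syllable intervals from a detection mask
#'
#' Time bins containing at least one detected pixel form runs; runs whose
#' separating silent gap is shorter than `min_gap_ms` are merged (merging
#' happens *before* the duration filter, so two sub-threshold fragments
#' close together can still form one valid syllable); merged runs shorter
#' than `min_syllable_ms` are discarded. Intervals are half-open
#' `[start_s, end_s)` on the audio clock, with each time bin owning
#' `[centre - dt/2, centre + dt/2)`.
#'
#' @param mask logical matrix (freq x time) from [binarize_and_clean()].
#' @param times frame-centre times, seconds (e.g. `spec$t`).
#' @param cfg a [seg_config()].
#' @return data.frame with `start_s`, `end_s`, `duration_ms` (features
#'   unfilled; see [compute_features()]).
#' @export
extract_syllables <- function(mask, times, cfg = seg_config()) {
  if (ncol(mask) != length(times)) stop("mask and time axis not conformable")
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_ms = numeric(0))
  active <- colSums(mask) > 0
  if (!any(active)) return(empty)
  if (length(times) < 2L) stop("need at least two time bins")
  dt <- times[2] - times[1]
  r <- rle(active)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  on <- which(r$values)
  s <- times[starts_idx[on]] - dt / 2
  e <- times[ends_idx[on]] + dt / 2
  # merge runs separated by < min_gap_ms
  if (length(s) > 1L) {
    gap <- s[-1L] - e[-length(e)]
    merge <- gap < cfg$min_gap_ms / 1000 - 1e-9
    grp <- cumsum(c(TRUE, !merge))
    s <- s[!duplicated(grp)]
    e <- e[!duplicated(grp, fromLast = TRUE)]
  }
  keep <- (e - s) >= cfg$min_syllable_ms / 1000 - 1e-9
  s <- as.numeric(s[keep]); e <- as.numeric(e[keep])
  if (length(s) == 0L) return(empty)
  data.frame(start_s = s, end_s = e, duration_ms = (e - s) * 1000)
}

#' Compute syllable acoustic features
#'
#' For each syllable, the spectrogram slab covering its interval is
#' re-thresholded at the higher `feature_z` (on the same per-row robust
#' scale used for detection) to strip residual noise. Duration is
#' `end - start`; mean frequency is the unweighted mean of the frequencies
#' of all surviving pixels; bandwidth is the highest minus the lowest
#' surviving frequency. Syllables whose slab retains no pixel at the
#' stricter threshold keep `NA` features but are not dropped.
#'
#' @param spec a [compute_spectrogram()] result.
#' @param syllables data.frame from [extract_syllables()].
#' @param cfg a [seg_config()].
#' @param row_stats optional precomputed row statistics.
#' @return `syllables` with `mean_freq_hz` and `bandwidth_hz` columns added.
#' @export
compute_features <- function(spec, syllables, cfg = seg_config(),
                             row_stats = NULL) {
  rs <- if (is.null(row_stats)) spectrogram_row_stats(spec) else row_stats
  z <- (rs$logp - rs$med) / rs$mad
  n <- nrow(syllables)
  mf <- rep(NA_real_, n); bw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cols <- which(spec$t >= syllables$start_s[i] - 1e-12 &
                    spec$t < syllables$end_s[i])
    # frames whose analysis window straddles the syllable boundary mix
    # the on/offset transient and splatter spectrally; drop them when the
    # syllable is long enough to afford it
    trim <- ceiling(cfg$stft_window / cfg$stft_hop)
    if (length(cols) > 2L * trim + 4L)
      cols <- cols[(trim + 1L):(length(cols) - trim)]
    if (length(cols) == 0L) next
    slab <- rs$logp[, cols, drop = FALSE]
    floor_lp <- max(slab) - cfg$leakage_db * log(10) / 10
    hit <- which(z[, cols, drop = FALSE] >= cfg$feature_z &
                   slab >= floor_lp, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    fr <- spec$f[hit[, 1L]]
    mf[i] <- mean(fr)
    bw[i] <- max(fr) - min(fr)
  }
  syllables$mean_freq_hz <- mf
  syllables$bandwidth_hz <- bw
  syllables
}

#' Group syllables into songs
#'
#' A song is a succession of syllables flanked by at least `song_gap_s` of
#' syllable-free time: a new song starts whenever the silent gap from the
#' previous syllable's end to the next syllable's start is `>= song_gap_s`
#' (the comparison is inclusive). A song's onset is its first syllable's
#' start.
#'
#' @param syllables time-sorted data.frame with `start_s`, `end_s`.
#' @param cfg a [seg_config()].
#' @return list with `syllables` (input plus `song_id`) and `songs`
#'   (data.frame: `song_id`, `onset_s`, `offset_s`, `n_syllables`).
#' @export
group_songs <- function(syllables, cfg = seg_config()) {
  n <- nrow(syllables)
  songs0 <- data.frame(song_id = integer(0), onset_s = numeric(0),
                       offset_s = numeric(0), n_syllables = integer(0))
  if (n == 0L) return(list(syllables = cbind(syllables, song_id = integer(0)),
                           songs = songs0))
  if (is.unsorted(syllables$start_s)) stop("syllables must be time-sorted")
  gap <- syllables$start_s[-1L] - syllables$end_s[-n]
  song_id <- cumsum(c(TRUE, gap >= cfg$song_gap_s - 1e-9))
  syllables$song_id <- song_id
  songs <- data.frame(
    song_id = unique(song_id),
    onset_s = syllables$start_s[!duplicated(song_id)],
    offset_s = syllables$end_s[!duplicated(song_id, fromLast = TRUE)],
    n_syllables = as.integer(tabulate(song_id)))
  list(syllables = syllables, songs = songs)
}

#' Segment a USV recording end to end
#'
#' Runs the full parsing chain: band-restricted spectrogram, robust
#' binarization with neighbourhood cleaning, syllable extraction, feature
#' computation, and song grouping.
#'
#' @param waveform numeric audio samples.
#' @param fs sampling rate, Hz.
#' @param cfg a [seg_config()].
#' @return list with `syllables` (start_s, end_s, duration_ms,
#'   mean_freq_hz, bandwidth_hz, song_id) and `songs` (song_id, onset_s,
#'   offset_s, n_syllables).
#' @export
segment_usv <- function(waveform, fs, cfg = seg_config()) {
  spec <- compute_spectrogram(waveform, fs, cfg)
  rs <- spectrogram_row_stats(spec)
  mask <- binarize_and_clean(spec, cfg, row_stats = rs)
  syl <- extract_syllables(mask, spec$t, cfg)
  syl <- compute_features(spec, syl, cfg, row_stats = rs)
  group_songs(syl, cfg)
}
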