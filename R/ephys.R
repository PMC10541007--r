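# Extracellular analysis: common-median referencing, threshold-crossing
# spike detection, peri-event time histograms, and permutation-based
# responsiveness.

#' Spike-detection configuration
#'
#' @param threshold_k detection threshold in SD units (default 10: only
#'   crossings greater than 10 SDs from the mean are kept, which keeps the
#'   recording far above chance crossings and obviates spike sorting).
#' @param refractory_ms crossings closer than this collapse to the
#'   largest-amplitude sample, ms.
#' @return list of class `spike_config`.
#' @export
spike_config <- function(threshold_k = 10, refractory_ms = 1) {
  if (threshold_k <= 0) stop("threshold_k must be positive")
  structure(list(threshold_k = threshold_k, refractory_ms = refractory_ms),
            class = "spike_config")
}

#' Common-median reference
#'
#' Subtracts, at every time sample, the across-channel median from every
#' channel. Signals shared identically by all channels (mains pickup,
#' movement artifact) are removed exactly; a spike confined to one channel
#' is untouched as long as it does not move the median.
#'
#' @param x numeric matrix, channels x samples, with >= 3 channels.
#' @return referenced matrix of the same shape.
#' @export
common_median_reference <- function(x) {
  if (!is.matrix(x) || nrow(x) < 3L) stop("need a matrix with >= 3 channels")
  med <- apply(x, 2L, stats::median)
  x - rep(med, each = nrow(x))
}

#' Threshold-crossing spike detection on one channel
#'
#' The channel SD is estimated robustly (MAD / 0.6745) so that the spikes
#' themselves do not inflate it. Samples whose absolute deviation from the
#' channel mean exceeds `threshold_k * SD` are crossings; crossings closer
#' than the refractory period are collapsed into one event at the
#' largest-amplitude sample, and the spike time is that extremum.
#'
#' @param x numeric voltage trace for one channel.
#' @param fs sampling rate, Hz.
#' @param cfg a [spike_config()].
#' @return numeric vector of spike times, seconds, strictly increasing.
#' @export
detect_spikes <- function(x, fs, cfg = spike_config()) {
  if (length(x) < fs) stop("need at least 1 s of signal for SD estimation")
  s <- stats::mad(x)
  if (s <= 0) stop("zero-variance signal")
  dev <- abs(x - mean(x))
  idx <- which(dev > cfg$threshold_k * s)
  if (length(idx) == 0L) return(numeric(0))
  refr <- cfg$refractory_ms / 1000 * fs
  grp <- cumsum(c(1L, as.integer(diff(idx) > refr)))
  times <- vapply(split(idx, grp), function(ii) {
    ii[which.max(dev[ii])]
  }, numeric(1))
  as.numeric((sort(times) - 1) / fs)
}

# per-trigger binned spike counts, pooled; spikes must be sorted
pooled_bin_counts <- function(spikes, triggers, edges) {
  nb <- length(edges) - 1L
  counts <- integer(nb)
  for (tr in triggers) {
    i0 <- findInterval(tr + edges[1L] - 1e-12, spikes) + 1L
    i1 <- findInterval(tr + edges[nb + 1L] - 1e-12, spikes)
    if (i1 < i0) next
    rel <- spikes[i0:i1] - tr
    b <- findInterval(rel, edges, rightmost.closed = FALSE)
    b <- b[b >= 1L & b <= nb]
    tb <- tabulate(b, nbins = nb)
    counts <- counts + tb
  }
  counts
}

#' Peri-event time histogram
#'
#' Trial-averaged binned firing rate aligned on the triggers:
#' `rate(bin) = total spikes in bin across trials / (n_trials * bin_s)`.
#' Bins are half-open `[left, right)` on the trigger-relative clock.
#'
#' @param spikes spike times for one unit, seconds (sorted).
#' @param triggers event times, seconds (song onsets or SE onsets).
#' @param pre_s,post_s window extent, seconds.
#' @param bin_s bin width, seconds.
#' @return list of class `peth`: `edges`, `mid`, `rate` (Hz), `counts`,
#'   `n_trials`, `bin_s`; permutation fields unfilled until
#'   [responsiveness_test()].
#' @export
compute_peth <- function(spikes, triggers, pre_s = 5, post_s = 5,
                         bin_s = 0.25) {
  if (length(triggers) == 0L) stop("need at least one trigger")
  spikes <- sort(spikes)
  edges <- seq(-pre_s, post_s, by = bin_s)
  counts <- pooled_bin_counts(spikes, triggers, edges)
  structure(list(edges = edges,
                 mid = edges[-length(edges)] + bin_s / 2,
                 rate = counts / (length(triggers) * bin_s),
                 counts = counts,
                 n_trials = length(triggers),
                 bin_s = bin_s, pre_s = pre_s, post_s = post_s,
                 null_mean = NULL, null_sd = NULL,
                 responsive = NA, sign = NA_integer_,
                 latency_s = NA_real_),
            class = "peth")
}

#' Permutation test for event responsiveness of a unit
#'
#' The null PETH distribution is built by recomputing the PETH on
#' `n_perm` surrogate trigger sets (same trial count, uniform over the
#' valid span of the recording). A unit is responsive when at least
#' `min_consec` consecutive bins deviate by `z_thresh` or more null-SDs
#' from the null mean, with a common sign; the response sign is the sign
#' of the first such run, and the latency is the left edge of its first
#' bin. The bare 2-SD rule is multiplicity-uncorrected, so the run-length
#' requirement (default 2) is the minimal correction; set
#' `min_consec = 1` for the permissive single-bin criterion.
#'
#' @param spikes spike times, seconds.
#' @param triggers real event times, seconds.
#' @param span two-element recording span `(t0, t1)`, seconds, from which
#'   surrogate triggers are drawn.
#' @param pre_s,post_s,bin_s PETH geometry (see [compute_peth()]).
#' @param n_perm number of surrogate trigger sets (>= 100).
#' @param z_thresh deviation threshold in null-SD units (default 2).
#' @param min_consec run length required to call a response.
#' @param response_window restrict the search for deviant runs to this
#'   trigger-relative interval, seconds; default the whole window.
#' @param seed RNG seed.
#' @return a `peth` with `null_mean`, `null_sd`, `z`, `responsive`,
#'   `sign`, `latency_s` filled.
#' @export
responsiveness_test <- function(spikes, triggers, span,
                                pre_s = 5, post_s = 5, bin_s = 0.25,
                                n_perm = 1000, z_thresh = 2,
                                min_consec = 2L, response_window = NULL,
                                seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  lo <- span[1] + pre_s; hi <- span[2] - post_s
  if (hi <= lo) stop("recording span too short for the PETH window")
  spikes <- sort(spikes)
  obs <- compute_peth(spikes, triggers, pre_s, post_s, bin_s)
  nb <- length(obs$rate)
  ntr <- length(triggers)
  null_rates <- with_seed(seed, {
    m <- matrix(0, n_perm, nb)
    for (p in seq_len(n_perm)) {
      trig <- runif(ntr, lo, hi)
      m[p, ] <- pooled_bin_counts(spikes, trig, obs$edges) / (ntr * bin_s)
    }
    m
  })
  obs$null_mean <- colMeans(null_rates)
  obs$null_sd <- apply(null_rates, 2L, sd)
  sdsafe <- ifelse(obs$null_sd > 0, obs$null_sd, Inf)
  z <- (obs$rate - obs$null_mean) / sdsafe
  obs$z <- z
  if (is.null(response_window)) response_window <- c(-pre_s, post_s)
  inwin <- obs$mid >= response_window[1] & obs$mid <= response_window[2]
  sig <- ifelse(abs(z) >= z_thresh & inwin, sign(z), 0)
  r <- rle(sig)
  runs <- which(r$values != 0 & r$lengths >= min_consec)
  obs$responsive <- length(runs) > 0L
  if (obs$responsive) {
    first <- runs[1L]
    start_bin <- sum(r$lengths[seq_len(first - 1L)]) + 1L
    obs$sign <- as.integer(r$values[first])
    obs$latency_s <- obs$edges[start_bin]
  }
  obs$n_perm <- n_perm
  obs
}

#' Categorize a unit from its song and SE responsiveness
#'
#' @param song_peth,se_peth `peth` objects with responsiveness filled
#'   (see [responsiveness_test()]).
#' @return list of class `unit_category`: `se_responsive`,
#'   `song_responsive`, `category` in
#'   `{"SE-only", "Song-only", "Both", "None"}`.
#' @export
categorize_unit <- function(song_peth, se_peth) {
  if (is.na(song_peth$responsive) || is.na(se_peth$responsive))
    stop("run responsiveness_test() on both PETHs first")
  se <- isTRUE(se_peth$responsive)
  song <- isTRUE(song_peth$responsive)
  category <- if (se && song) "Both" else if (se) "SE-only" else
    if (song) "Song-only" else "None"
  structure(list(se_responsive = se, song_responsive = song,
                 category = category),
            class = "unit_category")
}

#' Summarize unit categories across a population
#'
#' Tallies the responsive matrix: how many units respond at all, how many
#' carry an SE flag or a song flag (categories overlap in `Both`), and the
#' SE-responsive percentage among responders.
#'
#' @param categories list of `unit_category` objects, or a data.frame with
#'   logical columns `se_responsive`, `song_responsive`.
#' @return list: `n_units`, `n_responsive`, `n_se`, `n_song`, `n_both`,
#'   `pct_responsive`, `pct_se_of_responsive`, `table` (category counts).
#' @export
summarize_unit_categories <- function(categories) {
  if (is.data.frame(categories)) {
    se <- categories$se_responsive; song <- categories$song_responsive
  } else {
    se <- vapply(categories, `[[`, logical(1), "se_responsive")
    song <- vapply(categories, `[[`, logical(1), "song_responsive")
  }
  resp <- se | song
  cat_lab <- ifelse(se & song, "Both",
                    ifelse(se, "SE-only", ifelse(song, "Song-only", "None")))
  list(n_units = length(resp),
       n_responsive = sum(resp),
       n_se = sum(se), n_song = sum(song), n_both = sum(se & song),
       pct_responsive = 100 * mean(resp),
       pct_se_of_responsive = if (any(resp)) 100 * sum(se) / sum(resp)
                              else NA_real_,
       table = table(factor(cat_lab,
                            levels = c("SE-only", "Song-only", "Both", "None"))))
}
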