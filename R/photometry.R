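# Fiber-photometry analysis: delta-F/F, event-triggered averages with a
# random-trigger permutation null, and Ca2+ onset estimation by 10-90%
# line-fit extrapolation.

#' Anti-aliased decimation of a photometry trace
#'
#' Hardware oversamples fluorescence far beyond Ca2+ indicator dynamics
#' (e.g. 50 kHz); analysis runs at ~1 kHz. Decimation is staged in integer
#' factors of at most 10, each an 8th-order Chebyshev low-pass followed by
#' subsampling (via [signal::decimate()]).
#'
#' @param x numeric trace.
#' @param fs input sampling rate, Hz.
#' @param target_fs output rate, Hz; `fs / target_fs` must be an integer.
#' @return list with `x` (decimated trace) and `fs` (= `target_fs`).
#' @export
decimate_trace <- function(x, fs, target_fs = 1000) {
  q <- fs / target_fs
  if (abs(q - round(q)) > 1e-9) stop("fs / target_fs must be an integer")
  q <- round(q)
  while (q > 1) {
    f <- if (q %% 10 == 0) 10 else if (q %% 5 == 0) 5 else
         if (q %% 2 == 0) 2 else q
    if (f > 13) stop("cannot factor decimation ratio ", q,
                     " into steps <= 13")
    x <- signal::decimate(x, f)
    q <- q / f
  }
  list(x = x, fs = target_fs)
}

#' Compute delta-F/F from a raw fluorescence trace
#'
#' Baseline fluorescence `f0` is the 10th percentile of the whole-session
#' trace (after optional decimation), and `dff = (f - f0) / f0`. An
#' optional linear detrend (off by default) removes slow drift before the
#' percentile is taken.
#'
#' @param raw numeric raw fluorescence; must be positive-valued.
#' @param fs sampling rate of `raw`, Hz.
#' @param target_fs analysis rate, Hz; traces sampled faster are decimated
#'   (see [decimate_trace()]). Set `NULL` to keep `fs`.
#' @param f0_quantile baseline percentile (default 0.10).
#' @param detrend if `TRUE`, subtract a least-squares line (re-adding its
#'   mean) before computing `f0`.
#' @return list of class `photometry_trace`: `raw`, `dff`, `f0`, `fs`.
#' @export
compute_dff <- function(raw, fs, target_fs = 1000, f0_quantile = 0.10,
                        detrend = FALSE) {
  if (any(raw <= 0)) stop("raw trace must be positive-valued")
  if (!is.null(target_fs) && fs > target_fs) {
    d <- decimate_trace(raw, fs, target_fs)
    raw <- d$x; fs <- d$fs
  }
  if (detrend) {
    tt <- seq_along(raw)
    fit <- lm.fit(cbind(1, tt), raw)
    raw <- raw - fit$fitted.values + mean(raw)
  }
  f0 <- as.numeric(quantile(raw, f0_quantile, names = FALSE))
  if (f0 <= 0) stop("baseline f0 <= 0; trace unusable")
  structure(list(raw = raw, dff = (raw - f0) / f0, f0 = f0, fs = fs),
            class = "photometry_trace")
}

# index matrix of event windows; triggers whose window leaves the trace
# are dropped
window_indices <- function(n, fs, triggers, pre_s, post_s) {
  rel <- seq(-round(pre_s * fs), round(post_s * fs))
  centre <- round(triggers * fs) + 1L
  ok <- centre + rel[1L] >= 1L & centre + rel[length(rel)] <= n
  list(rel = rel, centre = centre[ok], n_dropped = sum(!ok))
}

#' Event-triggered average of delta-F/F
#'
#' Mean over events of dff segments aligned on the trigger times (e.g. the
#' first syllable of each song). Triggers whose window would leave the
#' recording are dropped, with the count reported.
#'
#' @param trace a [compute_dff()] result.
#' @param triggers event times, seconds.
#' @param pre_s,post_s window extent before/after the trigger, seconds.
#' @return list of class `triggered_average`: `t` (seconds, relative to
#'   trigger), `mean`, `n_events`, `n_dropped`, `fs`; the permutation
#'   fields (`null_mean`, `null_sd`, `p_value`) are unfilled until
#'   [permutation_bands()].
#' @export
triggered_average <- function(trace, triggers, pre_s = 5, post_s = 5) {
  w <- window_indices(length(trace$dff), trace$fs, triggers, pre_s, post_s)
  if (length(w$centre) == 0L) stop("no usable triggers (all windows clipped)")
  idx <- outer(w$centre, w$rel, `+`)
  seg <- matrix(trace$dff[idx], nrow = length(w$centre))
  structure(list(t = w$rel / trace$fs,
                 mean = colMeans(seg),
                 n_events = length(w$centre),
                 n_dropped = w$n_dropped,
                 fs = trace$fs,
                 pre_s = pre_s, post_s = post_s,
                 null_mean = NULL, null_sd = NULL, p_value = NULL),
            class = "triggered_average")
}

#' Random-trigger permutation bands and p-value for a triggered average
#'
#' Generates `n_perm` surrogate trigger sets, each of `n_events` times
#' drawn uniformly over the valid range of the recording, and recomputes
#' the triggered mean for each. `null_mean`/`null_sd` are the per-timepoint
#' moments of those surrogate averages (the "+/- 2 SD of the permutation
#' test average" band). The single-session p-value compares peak
#' statistics: `p = (1 + #draws with peak >= observed peak) / (n_perm + 1)`.
#'
#' @param trace a [compute_dff()] result (the same trace the average came
#'   from).
#' @param avg a [triggered_average()] result.
#' @param n_perm number of permutation draws (>= 100).
#' @param seed RNG seed for the surrogate trigger times.
#' @return `avg` with `null_mean`, `null_sd` and `p_value` filled.
#' @export
permutation_bands <- function(trace, avg, n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  n <- length(trace$dff); fs <- trace$fs
  rel <- seq(-round(avg$pre_s * fs), round(avg$post_s * fs))
  lo <- (1L - rel[1L]) / fs
  hi <- (n - rel[length(rel)] - 1L) / fs
  if (hi <= lo) stop("recording too short to place permutation windows")
  ne <- avg$n_events
  with_seed(seed, {
    centre <- round(runif(n_perm * ne, lo, hi) * fs) + 1L
    idx <- outer(centre, rel, `+`)
    seg <- matrix(trace$dff[idx], nrow = n_perm * ne)
    # mean over the ne events within each draw
    grp <- rep(seq_len(n_perm), each = ne)
    null_means <- rowsum(seg, grp) / ne
    avg$null_mean <- colMeans(null_means)
    avg$null_sd <- apply(null_means, 2L, sd)
    peaks <- apply(null_means, 1L, max)
    avg$p_value <- (1 + sum(peaks >= max(avg$mean))) / (n_perm + 1)
    avg$n_perm <- n_perm
    avg
  })
}

#' Estimate the Ca2+ onset time from a triggered average
#'
#' The average is baseline-subtracted (mean of the earliest 20% of the
#' window), its peak located inside the search window, and a straight line
#' is fit by least squares to the contiguous rising segment whose
#' amplitude lies between 10% and 90% of the peak. The onset is where that
#' line extrapolates to zero (the pre-event baseline level). A negative
#' value means activity rises before the trigger.
#'
#' @param avg a [triggered_average()] result.
#' @param search_s two-element window (seconds, relative to trigger) in
#'   which to look for the peak; defaults to the full window.
#' @param baseline_frac fraction of the earliest part of the window used
#'   as baseline (default 0.2).
#' @return onset time in seconds relative to the trigger, with the fitted
#'   slope/intercept and the fitted sample indices as attributes.
#' @export
estimate_onset <- function(avg, search_s = NULL, baseline_frac = 0.2) {
  t <- avg$t; y <- avg$mean
  if (is.null(search_s)) search_s <- range(t)
  nb <- max(2L, floor(baseline_frac * length(t)))
  y0 <- y - mean(y[seq_len(nb)])
  inwin <- which(t >= search_s[1] & t <= search_s[2])
  if (length(inwin) < 3L) stop("search window too narrow")
  pk <- inwin[which.max(y0[inwin])]
  peak <- y0[pk]
  if (!(peak > 0)) stop("no positive peak in the search window")
  below <- which(y0[seq_len(pk)] < 0.1 * peak)
  if (length(below) == 0L) stop("rise begins before the window; widen pre_s")
  i_lo <- max(below) + 1L
  seg <- seq(i_lo, pk)
  seg <- seg[y0[seg] <= 0.9 * peak]
  if (length(seg) < 3L) stop("rise too fast to fit (fewer than 3 samples in the 10-90% band)")
  fit <- lm(yy ~ tt, data = data.frame(tt = t[seg], yy = y0[seg]))
  b <- coef(fit)
  if (!(b[2] > 0)) stop("fitted rise has non-positive slope")
  onset <- as.numeric(-b[1] / b[2])
  attr(onset, "slope") <- as.numeric(b[2])
  attr(onset, "intercept") <- as.numeric(b[1])
  attr(onset, "fit_idx") <- seg
  onset
}

#' One-call photometry session analysis
#'
#' Convenience wrapper: delta-F/F, song-onset-triggered average,
#' permutation bands and onset estimate.
#'
#' @param raw raw fluorescence trace.
#' @param fs its sampling rate, Hz.
#' @param triggers song-onset times, seconds.
#' @param pre_s,post_s window extent, seconds.
#' @param n_perm permutation draws.
#' @param search_s onset search window (passed to [estimate_onset()]).
#' @param seed RNG seed.
#' @param target_fs analysis rate (see [compute_dff()]).
#' @return list: `trace`, `avg` (with null bands and p), `onset_s`
#'   (NA if the onset fit fails, with the error message in
#'   `onset_error`).
#' @export
photometry_session <- function(raw, fs, triggers, pre_s = 5, post_s = 5,
                               n_perm = 1000, search_s = NULL, seed = NULL,
                               target_fs = 1000) {
  trace <- compute_dff(raw, fs, target_fs = target_fs)
  avg <- triggered_average(trace, triggers, pre_s, post_s)
  avg <- permutation_bands(trace, avg, n_perm = n_perm, seed = seed)
  onset <- tryCatch(estimate_onset(avg, search_s = search_s),
                    error = function(e) structure(NA_real_, msg = conditionMessage(e)))
  list(trace = trace, avg = avg,
       onset_s = as.numeric(onset),
       onset_error = attr(onset, "msg"))
}
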