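---
title: "Methods: USV song segmentation and event-triggered neural analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: USV song segmentation and event-triggered neural analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`songpeth` analyses courtship ultrasonic vocalization (USV) sessions in
which a male mouse is repeatedly presented with a female (a *social
exposure*, SE) while audio and neural signals are recorded. This
vignette is the package's account of its methods: the models and rules
each stage implements, the parameters that matter and why they default
to what they do, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## Syllable and song parsing

The behavioural unit of every downstream analysis is the *syllable*: a
continuous frequency modulation in the spectrogram lasting at least 8 ms
with at least 16 ms of surrounding silence. A *song* is a succession of
syllables flanked by at least 10 s of quiet; its onset — the first
syllable's start — is the trigger for all song-locked analyses. The 10 s
rule matters for interpretation: it guarantees that activity before a
song onset reflects pre-vocal state rather than the tail of an earlier
bout.

The parser works on a magnitude-squared short-time Fourier transform
restricted to 20–125 kHz:

* **STFT geometry.** Hann window of 512 samples, hop 128. At 250 kHz this
  gives ~2 ms windows every ~0.51 ms and a 488 Hz row spacing, resolving
  the 8 ms / 16 ms duration rules with more than an order of magnitude
  of margin. Frames are computed in chunks and out-of-band rows are
  discarded as they are produced, so an hour-scale session never holds a
  full-band complex spectrogram in memory.
* **Pixel detection** (`detect_z`, default 4). A pixel is detected when
  its *log*-power exceeds its frequency row's median by `detect_z`
  scaled MADs. Row-wise robust statistics make steady narrowband
  interference invisible, since such noise raises its own row's median.
  The z-score is taken on log-power deliberately: raw periodogram power
  is exponential-tailed, and a 4-MAD cut on that scale would pass a few
  percent of noise pixels; on the log scale the null tail is doubly
  exponential and the same nominal threshold yields an essentially zero
  pixel-level false rate. This is what makes the package's
  zero-false-syllable behaviour on song-free noise attainable at the
  documented default.
* **Isolation cleaning** (`square_size = 3`, `min_neighbors = 1`). A
  detected pixel is removed if fewer than one *other* detected pixel
  lies in the 3×3 window centred on it — the most literal reading of
  removing pixels "isolated" within a square of size 3. Real syllable
  ridges are contiguous and survive; stray single pixels do not.
* **Run merging and the duration filter.** Time bins containing any
  detected pixel form runs; runs separated by less than 16 ms merge
  *before* the 8 ms minimum-duration filter is applied. The order
  matters: two sub-8 ms fragments 10 ms apart are one valid syllable,
  and filtering first would delete both. All threshold comparisons are
  inclusive (`>=`) on the discretized grid, and intervals are half-open
  `[start, end)` with each time bin owning `centre ± hop/2`.

### Syllable features

Duration is `end − start`. Mean frequency and bandwidth are computed
from the syllable's spectrogram slab after a second, stricter cleaning:

* a higher robust threshold (`feature_z`, default 6 versus 4 for
  detection), as feature estimates are more sensitive to stray pixels
  than interval estimates;
* a *peak-relative leakage floor* (`leakage_db`, default 8): pixels more
  than 8 dB below the slab's loudest pixel are discarded. This floor is
  what makes bandwidth independent of loudness. Any purely
  noise-relative threshold fails here: a louder syllable pushes more of
  its Hann mainlobe skirt above the noise, and measured bandwidth grows
  with SNR by one to two bins per edge. Eight dB sits above within-ridge
  power fluctuation but below the ≥6 dB attenuation of skirt bins one
  bin off the ridge, localizing each band edge to about one bin;
* *edge-frame trimming*: frames whose analysis window straddles the
  syllable boundary mix the onset/offset transient and splatter
  spectrally, so when the syllable is long enough the first and last
  `window/hop` frames of the slab are dropped.

Mean frequency is the unweighted mean of the surviving pixels'
frequencies; bandwidth is highest minus lowest surviving frequency. A
slab that retains no pixel at the stricter threshold keeps `NA` features
but the syllable itself is not dropped. One resolution caveat is
inherent: a sweep traversing more than a bin or two *within one analysis
window* (≳1 MHz/s at the default geometry) smears by that amount, and no
threshold choice can undo it.

## Fiber photometry

ΔF/F uses the whole-session 10th percentile as F₀ — a global rather than
rolling baseline, which is the literal definition and keeps ΔF/F
comparable across the session; an optional linear detrend (off by
default) is available for drifting sessions. Hardware-rate traces
(tens of kHz) are decimated to 1 kHz before analysis, since indicator
dynamics live far below that; the staged Chebyshev/`filtfilt`
decimation applies a small constant passband gain (~1%) which cancels
exactly in the ΔF/F ratio.

The song-onset-triggered average is compared against a random-trigger
null: `n_perm` (default 1000) surrogate sets of the same number of
triggers are drawn uniformly over the valid span, and the per-timepoint
mean ± 2 SD of the surrogate averages forms the null band. For a single
per-session test the band is collapsed to a *peak statistic*: the
p-value is the add-one-corrected fraction of surrogate averages whose
peak reaches the observed peak. The max statistic makes the many
timepoints one test rather than many. Surrogate triggers are drawn with
no exclusion zone around real events; with seconds-scale transients and
minute-scale sessions the resulting null contamination is negligible,
and the choice keeps the null definition simple and configurable.

The Ca²⁺ onset is estimated from the average by baseline-subtracting the
earliest 20% of the window, locating the peak, walking back to the last
sample below 10% of peak, and fitting a least-squares line through the
contiguous rising samples between 10% and 90% of peak; the onset is
where the line crosses zero, i.e. the pre-event baseline level (the
"zero" of a baseline-subtracted average — the definition adopted here
since extrapolating to literal zero ΔF/F would depend on F₀ rather than
on the transient). Fewer than three samples in the 10–90% band is an
error ("rise too fast to fit") rather than a silent two-point fit. On a
saturating-exponential rise the chord extrapolation lands slightly
early; with GCaMP6s-like kinetics (rise constant ~0.2 s) the bias is
about a tenth of a second, well inside the package's ±0.3 s recovery
tolerance.

## Electrophysiology

Preprocessing subtracts the across-channel median at every sample
(common-median reference), removing signals shared identically by all
channels while leaving single-channel spikes untouched. Spike detection
needs no sorting at high signal-to-noise: events are samples whose
absolute deviation from the channel mean exceeds `threshold_k` (default
10) robust SDs (MAD/0.6745, so the spikes themselves do not inflate the
estimate). Absolute deviation is used because extracellular spikes are
negative-dominant but stimulation artifacts are not; crossings within a
1 ms refractory window collapse to the largest-amplitude sample, which
defines the spike time.

PETHs use a −5…+5 s window with 0.25 s bins by default: the effects of
interest live at the 1–2 s scale, so quarter-second bins resolve them
while keeping per-bin counts stable for tens of trials.
`rate(bin) = total spikes across trials / (n_trials × bin_s)`, which
conserves spike mass exactly.

Responsiveness is a permutation test: the PETH is recomputed on `n_perm`
uniform surrogate trigger sets, and a unit is responsive when at least
`min_consec` (default 2) consecutive bins deviate ≥2 null-SDs with a
common sign. A bare per-bin 2 SD rule over 40 bins is
multiplicity-uncorrected (expected false-positive rate near one in
three); the two-consecutive-bins requirement is the minimal correction
that respects the temporal contiguity of real responses, and it is
configurable down to 1 for the permissive literal criterion. The
response sign is the sign of the first qualifying run and the latency is
its first bin's left edge.

## Song-Inducing vs Quiet conditioning

An SE is *Song-Inducing* when at least one song onset falls within
`[SE onset, SE offset + 5 s]` — anchored at the offset because
presentations are short (≤10 s) and a song beginning during the ongoing
SE clearly counts; a song is *isolated* when its onset is at least 5 s
after every earlier SE offset and outside all SEs. Each song attaches to
the nearest preceding qualifying SE.

Per unit, the SE-triggered PETH is computed separately for the two
outcome classes after three admission rules: the unit must exceed 1 Hz
average rate during the SE epochs (below that, the ΔPETH estimate is
dominated by counting noise), at most the first 40 SEs in session order
are used (a cap with no stated selection rule; "first in time" is the
reproducible choice), and both classes must be non-empty. The contrast
is scalarized over a `[0, 2]` s response window after SE onset — the SE
response is centred around 1 s after exposure — and this window is the
single most consequential free parameter of the analysis; it is
configurable and deliberately conspicuous in `conditioning_config()`.

The null distribution for each unit's
ΔPETH = mean response-window rate(Song-Inducing) − (Quiet)
comes from 1000 random relabelings of the SE outcomes preserving class
counts. Because the PETH mean over trials equals the mean of per-trial
rates, each shuffle reduces to permuting labels over the per-SE
response-window rates, which makes the exact test cheap. Categories use
two-sided permutation p-values with the add-one counting correction,
ties counting against rejection: the rate statistic is discrete, and
interpolated null quantiles with strict inequalities are measurably
anti-conservative on tied data. Song-Inducing and Quiet categories are
symmetric at α/2 each; everything else is Agnostic, and a unit with an
empty class is Agnostic-by-default with an explicit flag.

At the population level each unit's observed ΔPETH is standardized by
its own null SD, the null draws are standardized the same way and
pooled, and the signed difference of means (observed − pooled null) is
the rightward-shift statistic; its one-sided p-value treats each shuffle
index as one pooled null draw across units.

## The synthetic-session generator

The generator exists so that every stage above can be validated by
parameter recovery with known ground truth. It emulates exactly the
statistical structure the analyses assume:

* **Audio.** Syllables are single-component sinusoid-FM tone bursts:
  carrier drawn per syllable (default 77.5 ± 8 kHz, matching courtship
  repertoires), instantaneous frequency sweeping the programmed
  bandwidth (default 12 kHz) as one full sine cycle that starts and ends
  at the carrier — so the band extremes fall in the syllable interior,
  away from the trimmed edge frames — with 1 ms raised-cosine ramps,
  against white Gaussian noise at a configured broadband SNR (default
  20 dB). Durations (15–50 ms) and gaps (40–120 ms) respect the 8/16 ms
  parsing rules by construction.
* **Behaviour.** SEs are uniform-random with enforced minimum spacing
  (default 20 s — at 15 s, a slow song latency plus song duration can
  leave inter-song gaps under 10 s and violate the song definition the
  parser relies on). Each SE elicits a song with probability 0.65, the
  observed rate of song-inducing presentations, at a log-normal latency
  with ~1–2 s mode truncated to 0.5–3 s. Isolated songs can be placed in
  SE-free stretches. The generator *errors* rather than silently bending
  its own rules when the requested events cannot be packed.
* **Photometry.** One double-exponential transient per song
  (`(1 − e^{−t/τr}) e^{−t/τd}`, unit peak; τr = 0.2 s, τd = 1.5 s,
  GCaMP6s-like) with onset `lead_s` (default 2.3 s) before the song
  onset, over a positive baseline with Gaussian noise and optional
  drift.
* **Spikes.** Inhomogeneous Poisson by thinning, with
  `rate = baseline + amp · gain^[Song-Inducing] · K_SE + amp · K_song`
  per tuning class; `K_SE` is a Gaussian bump peaking 1 s after SE
  onset, `K_song` peaks 0.8 s *before* song onset. The outcome gain `g`
  is the planted ΔPETH effect. Optional raw voltage places a
  negative-dominant biphasic template (~1 ms) at each spike over unit
  noise, plus an optional common-mode signal for referencing tests.

Identical configuration and seed reproduce every output bit for bit.

What the generator does **not** emulate — and therefore what passing
recovery tests do *not* establish about real recordings: harmonic
stacks, syllable-type repertoire structure, amplitude modulation within
syllables, reverberation or movement-dependent Doppler in the audio;
hemodynamic or movement artifacts, bleaching beyond linear drift, or
isosbestic channels in photometry; bursting, refractory structure
beyond the detector's collapse window, electrode drift, or overlapping
units in the spike data; and any coupling of behaviour to motivation
over the session. Results on real data depend on those factors; the
tests establish correctness of the computations, not robustness to
every physiological nuisance.

## Problem sizes and determinism

The validation suite runs at desk scale by design: segmentation recovery
uses a ~110 s, 250 kHz session with 50 planted syllables in 5 songs;
photometry calibration uses 500 null sessions at reduced sampling rate
with 200 permutations each; onset recovery uses 50 sessions of 12
transients; ΔPETH calibration uses hundreds of single-unit simulations
with 40 SEs and 500 shuffles each. These sizes put Monte-Carlo error
comfortably inside the asserted tolerances while keeping the suite fast.
All randomness flows through explicit seeds; `with_seed` isolates each
seeded computation from the ambient RNG stream, so library calls never
perturb reproducibility.

## Known limitations

* The ΔPETH response window `[0, 2]` s conflates late SE responses with
  pre-song activity when songs follow SEs at ~1–2 s latency; with this
  design the two cannot be fully separated, and the package does not
  claim to.
* Bandwidth and mean frequency are STFT-resolution-limited (one bin per
  band edge at best; worse for very fast sweeps).
* The onset line fit assumes a single dominant rising phase; multimodal
  averages yield whichever peak wins inside the search window.
* Unit identity is an input (one unit per selected channel); the package
  deliberately contains no spike sorter.
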