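---
title: "Scoring resting-state M/EEG epochs by spectral self-similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring resting-state M/EEG epochs by spectral self-similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epochscore)
```

## The model

`epochscore` treats a resting-state recording as a set of exchangeable,
fixed-length epochs drawn from one stationary spectral process, and defines an
epoch's quality as its spectral typicality: the average Spearman correlation
between its Welch power spectral density and the PSDs of all other epochs of
the same channel, averaged across channels. The underlying assumptions are

* the clean portion of a resting-state recording is approximately spectrally
  stationary at the epoch scale, so clean epochs correlate highly with each
  other;
* artifacts (movement, muscle, electrode, line noise) deform the spectrum of
  the affected epoch, breaking its rank correlation with the rest;
* rank correlation, being invariant under strictly monotone transforms, makes
  the score insensitive to per-channel gain and to any monotone rescaling of
  the spectrum.

The score is relative within one recording. A recording that is uniformly bad
still has high-scoring epochs; the score orders epochs, it does not certify
absolute quality. Scores lie in [-1, 1]; a recording whose epochs are exact
copies of one segment scores exactly 1 everywhere.

No filtering, detrending or re-referencing happens inside the scorer:
preprocessing belongs to the caller, and the score should reflect the data as
given.

## Parameters that matter

* **Epoch length** (`epoch_length_s`, default 5 s). Segmentation is
  non-overlapping and contiguous from the first sample; tail samples that do
  not fill an epoch are discarded. One minute at 160 Hz gives twelve 5-s
  epochs. Shorter epochs increase spectral variance; longer epochs blur
  localized artifacts into more data.
* **Frequency range** (`freq_range`, default 1–40 Hz). The comparison range of
  the spectra, and also the denominator of relative band power. 1–40 Hz covers
  the classical EEG bands while excluding DC drift and most line-noise
  harmonics; it is always user-overridable.
* **Welch configuration** (`welch_config()`): Hann window, segment length
  `min(1 s, epoch length)` (1-s segments give 1 Hz resolution, the standard
  resolution/variance trade-off in resting-state work), 50 % overlap, mean
  (constant) detrend per segment, one-sided density scaling in µV²/Hz. An
  explicitly requested segment longer than the epoch is an error.
* **Selection size** (`k`, default 4 of 12): how many top-ranked epochs the
  caller keeps; the package reports the full ranking so any k can be taken.
* **Feature band** (`band_definition`, default alpha 8–13 Hz, inclusive
  edges): used by relative band power and as the default PLI band.

## Numerical conventions

* **Similarity diagonal included.** The per-channel score is the row mean of
  the similarity matrix *including* the unit diagonal. Since
  `mean_with_diag = ((n-1) * mean_without + 1) / n` is affine increasing, the
  ranking is provably identical under either convention; the inclusive form is
  the literal "average over the rows".
* **Ties.** Tied PSD values get mid-ranks (the classical Spearman convention);
  tied scores are ranked by ascending epoch index, making the ranking a
  deterministic, stable sort.
* **Degenerate spectra.** A constant PSD vector has zero rank variance and no
  defined correlation. The default is an explicit error naming the epoch and
  channel; `on_degenerate = "rank_last"` instead assigns score `-Inf` and
  ranks such epochs last, for pipelines that prefer flagging over failing.
* **Indices are 1-based** everywhere in R structures and human-readable
  output; JSON reports additionally carry a `ranking_0based` field for
  interoperability with 0-based tooling.
* **Relative power** uses inclusive band edges on bin-center frequencies and
  rectangle (bin-sum) integration, so a disjoint partition of the analysis
  range sums to exactly 1 and results are bit-reproducible. The denominator is
  the total power over the retained analysis range (default 1–40 Hz), not the
  full Nyquist band — a deliberate choice where the convention is genuinely
  open; it makes the feature independent of power outside the range the
  scorer itself sees.
* **Percentile** placement uses the empirical `<=` definition,
  `100 * #(d <= value) / N`.
* **Paired effect size** is `mean(diff) / sd(diff)` with the n−1 standard
  deviation; zero variance of differences is an error rather than a silent
  infinity, and `t = d * sqrt(n)` exactly.

## Phase lag index choices

PLI for a channel pair is the absolute time-average of the sign of the
wrapped instantaneous phase difference (`sign(sin(Δφ))`, with `sign(0) = 0`,
so exactly zero-lag coupling contributes nothing — the property that makes PLI
insensitive to volume conduction). Phases come from the analytic signal of the
band-limited channel.

Two choices here were genuinely open and are package decisions, not
reconstructions:

* **Band**: default alpha 8–13 Hz (the contrast band of the evaluation
  scenario), configurable.
* **Filter**: a zero-phase FFT-domain band-pass with a raised-cosine
  transition band (default 1 Hz per side) instead of a forward–backward IIR.
  With no filter-design library among the package's dependencies, a
  hand-rolled Butterworth bilinear transform would have been the riskiest
  primitive in the code base; the FFT filter is exactly zero-phase, its
  passband is analytically known, and its circularity artifacts are confined
  to the epoch edges, which are excluded anyway (5 % of samples per side by
  default) together with the analytic-signal transients.

## What the synthetic generator emulates

`synthetic_spec()` describes a stated world chosen once:

* 160 Hz sampling, 60 s duration, twelve 5-s epochs — the acquisition
  geometry of the motor-imagery baseline runs the method was designed around;
* a 1/f Gaussian background (`power ∝ 1/f^β`, β = 1, RMS 10 µV) built by
  spectral shaping of white noise, a construction whose spectrum is known in
  closed form and is used as the analytic oracle in the tests;
* a 10 Hz alpha sinusoid with channel-specific random phase, amplitude 5 µV
  in the eyes-open condition and twice that with eyes closed (the canonical
  alpha reactivity effect), optionally decaying by a fixed factor per epoch to
  model drowsiness drift (tests use 0.90/epoch, a strong but realistic
  vigilance decline over one minute);
* 16 channels — a desk-scale low-density montage; every group feature in the
  package is a channel mean, so channel count does not drive any contrast;
* cohorts of 30 subjects whose alpha amplitudes share a log-normal
  between-subject factor (sd 0.2) applied to both conditions, so the
  programmed EC/EO ratio is preserved per subject;
* three parametric artifact archetypes (broadband noise burst, 0.3 Hz
  high-amplitude drift, 50 Hz line burst) injected into every channel of a
  chosen epoch. No attempt is made to imitate real EOG/EMG morphology.

What it does **not** emulate: spatial covariance between channels (channels
are independent up to the shared artifact), non-sinusoidal alpha waveforms,
heteroscedastic measurement noise, channel-specific artifacts, or real
between-subject spectral diversity. A green synthetic test therefore
establishes that the machinery is correct and sensitive in the stated world —
not that the published effect sizes on real data are reproduced. On these
synthetic cohorts the EC−EO contrast is much cleaner than in real EEG, so
sweep effect sizes (d ≈ 8–10) are far larger than the ≈ 1.4 observed on real
recordings; the tests assert ordering and threshold properties (minimum d > 1,
decreasing d with later selections under programmed drift), not those
magnitudes.

Determinism contract: all randomness flows through R's default Mersenne-
Twister generator from a single integer seed; identical spec and seed give
bit-identical recordings on any platform with IEEE doubles.

## Evaluation design decisions

* The score-guided selection is computed independently per condition — each
  run has its own recording, its own scores and its own top-k — because each
  condition's artifacts are its own. This was an open design point.
* No multiple-testing correction is applied across the selection sweep: the
  object of interest is the distribution of effect sizes, not corrected
  inference on any single selection.
* The sweep's Cohen's d is signed as EC − EO, positive under the expected
  alpha increase with eyes closed.

## Known limitations

* The Welch estimator's bin adjacent to DC is biased low by segment-mean
  removal (the removed DC component's window main lobe overlaps it); the
  default 1 Hz lower edge keeps this out of the analysis range at default
  settings.
* The EDF writer requires an integer sampling rate (one-second records) and
  integer-µV physical range bounds; round-trip error is bounded by one
  16-bit quantization step of each channel's (widened) amplitude range.
* Replication of the published real-data numbers needs the external
  99-subject dataset and its (unpublished) 10-subject exclusion list; the
  evaluation machinery is implemented and tested, but the package ships no
  real data.
* The scorer assumes at least two epochs and two frequency bins; it does not
  score partial epochs at the recording tail (they are discarded).
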