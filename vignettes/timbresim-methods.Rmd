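---
title: "Modeling the perceptual similarity of short music clips: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the perceptual similarity of short music clips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modeling problem

Listeners can judge the similarity of music excerpts lasting only a few
hundred milliseconds. At that timescale there is essentially no melody,
harmony or rhythm to go by, so the judgment must rest largely on *timbre* —
the bundle of auditory attributes, other than pitch, loudness and duration,
that characterizes a sound's quality and source. A standard way to measure
such judgments is the constrained free-sorting paradigm: each participant
sorts 16 clips into 4 groups of 4 by perceived similarity of sound, and the
pairwise similarity of two clips is the fraction of participants who placed
them in the same group.

`timbresim` implements a complete modeling pipeline for such data:

1. extract scalar acoustic features per clip (two 24-feature sets),
2. normalize each feature column under one of five schemes,
3. form, for each of the 120 non-identical clip pairs, the absolute
   difference of the pair's feature values — a 120 × n design matrix `X`,
4. regress the pairwise similarities `y` on `X` with partial least-squares
   regression (SIMPLS), `y = Xβ + F` with `β = W*q'`,
5. select a sparse predictor subset via bootstrap percentile confidence
   intervals over clip resampling, and
6. evaluate every model on the set it was trained on *and* on a second,
   independent stimulus set (the generalization grid).

Because the original stimuli are commercial recordings and the behavioral
data are not public, the package ships a first-class synthetic-data module:
parametric audio synthesis with a genre-template structure, a reference
corpus generator, and a participant model that turns ground-truth distances
into noisy constrained sorts. Every downstream stage is tested against data
from this module.

## The synthetic-data generator

### Stimuli

A clip is a sum of sinusoidal partials plus band-limited Gaussian noise,
amplitude-modulated, peak-normalized to 0.9 and given 20 ms raised-cosine
fades (`generate_clip()`). Four genre templates (jazz, rock, pop, hiphop)
fix parameter ranges — fundamental frequency region, spectral tilt, noise
band and gain, modulation rate and depth — chosen so the genres separate on
spectral centroid, flatness and modulation features, i.e. so there is
genuine acoustic signal for the pipeline to find. Release years are drawn
uniformly from genre-specific decade bands (jazz 1960–79, rock 1970–89, pop
and hiphop 1990–2000), mirroring the genre–decade coupling of the study
design so that the release-date predictor is informative.
`generate_stimulus_set()` draws 4 clips per genre with within-genre jitter;
the two study durations are 400 and 800 ms at 44.1 kHz. The two duration
conditions are generated independently (no within-song pairing across
durations).

The reference corpus (`generate_corpus()`) follows the corpus recipe used
for corpus ranking: 110 synthetic "songs" per genre, each contributing ten
800 ms clips, i.e. 4,400 clips. A song is a narrowed draw from its genre
template; its clips jitter around the song's parameters.

### Participants

The sorting decision process of real participants is unobserved; only final
sorts are recorded. We therefore posit the simplest latent model that
produces graded similarities: a participant perceives the true pairwise
distances through additive symmetric Gaussian noise (`noise_sd`) and then
minimizes total within-group perceived distance over partitions into equal
groups, by local search — random equal-size start, then repeated
best-improving cross-group swaps, ties broken by the lowest item-index pair.
On small instances where exhaustive enumeration is feasible (8 items, 2
groups, 35 partitions) the local search attains the global optimum in ≥95%
of random instances, which the test suite verifies.

Ground-truth distances for simulation are weighted city-block distances over
a known feature subset, optionally plus an additive increment for
cross-genre pairs (`genre_bonus`, default 0.25) representing genre
information beyond the acoustic features. Knowing the generating support
makes parameter recovery measurable (`recovery_run()`).

### Defaults and what they emulate

* `participants = 500` per set: enough for similarity fractions with low
  Monte-Carlo error at laboratory-plus scale (estimates stabilize as
  1/√P, which the tests check).
* `noise_sd = 0.3` on the scale of rank-normalized feature distances
  (typical pairwise distances ≈ 0.3–1.5): produces graded similarities
  across the full [0, 1] range rather than deterministic sorts.
* Simulation sizes in the test suite are scaled down (tens of participants,
  hundreds of bootstrap replicates) where only correctness of the machinery
  is at stake; the statistical acceptance checks use the full B = 1000.

What the generator does **not** emulate: real music's nonstationarity within
a clip, correlated feature noise across clips of one song in the stimulus
sets, participant heterogeneity (every simulated participant shares one
noise level), and any response bias of the sorting interface. Passing tests
on synthetic data therefore demonstrate that the machinery is correct and
can recover known structure — not that real similarity data are predictable
to the same degree. Indeed synthetic genre templates separate far more
cleanly than commercial recordings, so evaluation-grid R² values on
synthetic data are much higher than anything reported for human data.

## Feature extraction

Both feature sets use identical framing: 25 ms frames with 1/2 overlap
(1,102 samples, rounded to even, hop 551) under a Hann window.

### Timbre descriptors (24)

Spectral descriptors are computed from an ERB-spaced gammatone band-energy
decomposition: per-frame power spectra are weighted by squared 4th-order
gammatone magnitude responses at 64 center frequencies spanning ~26 Hz to
the Nyquist frequency (bandwidth 1.019·ERB). Implementing the filterbank as
a frequency-domain weighting of framed power spectra (rather than a
time-domain IIR cascade) keeps corpus-scale extraction fast while providing
exactly what the descriptors consume: a nonnegative band × frame energy
matrix.

Ten per-frame descriptors — centroid, spread, skewness, kurtosis, slope,
decrease, rolloff (95%), flatness, crest, and spectrotemporal variation
(one minus the normalized correlation of consecutive frame spectra) — are
each summarized by their median and interquartile range over frames (frames
with zero energy are flagged undefined and excluded). All ten are computed
on the energy-normalized spectrum and are therefore invariant to global
gain. Four temporal descriptors complete the set: the frequency and relative
amplitude of the dominant energy modulation (envelope via full-wave
rectification → 4th-order Butterworth low-pass at 50 Hz → decimation to
~400 Hz → DC removal → zero-padded FFT peak in (0.5, 50] Hz), and the
median and IQR of the per-frame zero-crossing rate. A silent clip maps
every temporal descriptor to 0, with the undefined modulation frequency
mapped to 0 by convention.

The exact 24-descriptor inventory of the original study is not published in
full; this set covers every descriptor the study names (the four spectral
moments, decrease, flatness, spectrotemporal variation, crest, modulation
frequency/amplitude, zero-crossing statistics) and fixes the count at
10 × {median, IQR} + 4 = 24.

### MFCCs (24)

Per frame: power spectrum → 40 triangular Mel filters (HTK mel scale,
0 Hz–Nyquist) → log power → orthonormal DCT-II, keeping coefficients 1–12
(the 0th, overall-energy coefficient is excluded, so the set is
gain-invariant like the timbre descriptors). Δ-coefficients are
frame-to-frame first differences — the simplest reading of "first
derivative over time". Each of the 24 series is summarized by its median.
The log is clamped 80 dB below the clip's peak Mel power: without the
clamp, Mel bands containing only numerical leakage fluctuate wildly in log
units and contaminate the cepstrum of even a stationary tone. The MFCC
dialect (filter count, mel scale, 0th-coefficient exclusion, Δ window) is
not uniquely determined by convention; these choices are the most common
defaults and are recorded here rather than asserted as the original
study's.

## Normalization (N1–N5)

Each feature column is normalized independently; differently normalized
tables are never pooled. `n1` identity; `n2` range to [0, 1]; `n3` z-scores
(sample SD, L−1); `n4` within-set midrank/L (16 distinct values map to
1/16 … 1); `n5` rank against the 4,400-clip reference corpus, midrank for
values tied with corpus values and insertion rank (count ≤ x) otherwise, so
queries below/above the whole corpus map to 0/1. Midranks avoid
order-of-appearance artifacts; all schemes preserve within-column ordering
(n5 weakly — distinct queries inside one corpus gap share a rank).
Normalization applies to feature *values*, before distances are taken.

## Design matrix and response

Pairs are ordered column-major along the lower triangle — (2,1), (3,1), …,
(16,1), (3,2), … — an arbitrary but fixed convention recorded in all output
row names and shared by construction between `X`, the meta predictors and
`y`. The similarity matrix's diagonal is stored as 1 but flagged excluded:
identical pairs were never presented, and including them would trivially
inflate R². The genre predictor is binary (0 = same genre); the date
predictor is operationalized as |Δ release year|, the natural pairwise
distance for a scalar year (a shared-decade indicator would be the main
alternative).

## SIMPLS, component selection, bootstrap

`fit_simpls()` centers `X` and `y` and applies no variance scaling —
scaling is the job of the normalization schemes, and double-scaling would
silently change the model. Successive weight vectors maximize the
covariance of predictor and response scores under deflation of the
cross-product vector; predictor scores are mutually orthogonal (asserted to
1e−8), and at full rank the fit coincides with ordinary least squares
(asserted against the normal equations to 1e−8; with one predictor, against
the simple regression line to 1e−10). The headline component count is fixed
at k = 2; `select_k()` reproduces the selection by seeded 8-fold
cross-validation at the pair level (the CV unit is not documented in the
original study; clip-level folds would be the alternative), exploiting the
nestedness of SIMPLS components, with ties going to the smallest k.

Bootstrap selection reads "four randomly selected clips (drawn with
replacement)" literally: 4 draws with replacement, hence 1–4 distinct clips
removed per replicate, which reproduces the documented ~60% average of
surviving pairs — the closed form is (14/16)⁴ ≈ 0.586. Per replicate the
model is refit with k = 2 on surviving pairs; replicates whose surviving
design matrix falls below rank k are refit with the attainable rank (and
counted) rather than discarded, keeping B fixed. Percentile (0.025/0.975)
bounds define selection. Normalized values are computed once on the full
set and reused inside replicates (normalization precedes resampling in the
pipeline order); recomputing n4 ranks within each replicate is a possible
alternative the package does not currently implement. Meta predictors,
when included, participate in bootstrap and selection like any column.

A known property, measured by the acceptance suite: under a pure-noise
response the per-feature selection rate is around 6–12% rather than the
nominal 5%, because any two replicates share on average ~60% of their
pairs, so the bootstrap spread understates the sampling variability of β.
Users should read the selector as a pragmatic screening device, not a
calibrated 5% test.

## Evaluation grid

Every (feature set × normalization × full/sparse × train/test) cell fits on
the training set and predicts the test set's own normalized design matrix —
for n4 this means test-set-internal ranks, which is the scheme's
definition, while centers and coefficients come solely from training (no
leakage). Performance is the squared Pearson correlation between predicted
and observed similarities (not 1 − SSE/SST), with significance from the
two-sided t-transform at df = m − 2 = 118; predictions are not clipped to
[0, 1] since clipping would silently alter the correlation. All cells are
reported with their raw values and significance flags; nothing is
suppressed. With all options the acoustic grid has
3 × 5 × 2 × 4 = 120 cells.

## Numerical choices and degenerate inputs

* Fades: raised cosine, 20 ms; peak normalization to 0.9 (click-free,
  non-clipping).
* All-zero frames: spectral descriptors undefined, excluded from summaries;
  a fully silent clip yields zeroed temporal descriptors.
* Skewness/kurtosis on a single-band spectrum (spread 0): defined as 0.
* Constant feature columns: hard error under n2/n3, naming the feature.
* Constant response: zero coefficients, intercept at the constant.
* Local-search ties: lowest item-index pair, making participants
  deterministic given their seed.
* Every stochastic stage takes an explicit seed; the pipeline manifest
  records all of them, and re-running a configuration reproduces every
  output byte for byte.

## Limitations

* The descriptor inventory and MFCC dialect are plausible reconstructions
  of underdocumented choices, not certified reproductions.
* The participant model is one plausible decision process; real sorting
  strategies are unknown and may be non-metric.
* Bootstrap percentile selection is anti-conservative under this resampling
  scheme (see above).
* Synthetic stimuli are stationary textures; conclusions about real music
  require real audio and behavioral data, which the package can ingest
  (WAV + CSV) but does not provide.
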