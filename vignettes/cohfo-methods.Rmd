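---
title: "Detecting and analyzing coincident HFO bursts: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analyzing coincident HFO bursts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohfo)
library(dplyr)
```

High-frequency oscillations (HFOs) are transient bursts in the 60-500 Hz
range of intracranial EEG, generated by brief coordinated firing of local
neuronal assemblies. During verbal memory tasks, bursts on widely separated
cortical contacts co-occur within tens of milliseconds ("co-HFOs"), and this
global co-bursting is modulated by memory encoding and recall. `cohfo`
implements the full analysis chain for this phenomenon — single-burst
detection, peri-event coincidence analysis, sequence clustering with
surrogate controls, and the accompanying inference — together with a
synthetic LFP generator so that every stage can be validated against known
ground truth without access to protected clinical recordings.

## 1. The burst detector

Each channel is decomposed into `n_bands = 38` contiguous band-pass filters
with logarithmically spaced edges from 60 to 800 Hz. Kernels are Hamming
windowed-sinc FIR filters; the order follows from a 5 Hz transition
bandwidth (the `transition_width = 0.200` s parameter is the reciprocal of
that bandwidth), which is what lets the narrowest low bands — the lowest
band is only ~4.7 Hz wide — develop a usable passband. The -6 dB point
falls at the band edges, so adjacent passbands tile the range without gaps.
Filtering is performed with exact zero phase by applying the
delay-compensated symmetric kernel in the frequency domain; for a symmetric
FIR this is mathematically identical to time-domain filtering followed by
group-delay removal, preserves the -6 dB edge behavior, and leaves event
times unshifted (the cross-correlation peak between a filtered tone and its
input is at lag zero).

Within each band the Hilbert amplitude envelope is z-scored against a
centered 10 s sliding window (truncated at the recording edges; zero local
SD yields z = 0, flagged). Candidate segments are maximal runs of z above
the liberal threshold 2 lasting at least 3 cycles of the band center
frequency. Candidates that overlap in time *and* lie in the same or
adjacent bands merge transitively into events — an event is a connected
blob in time-frequency space. We require band adjacency because
narrow-band-filtered background noise fluctuates independently in distant
bands; merging on temporal overlap alone chains those unrelated
fluctuations into spurious whole-spectrum events whose maximum z trivially
exceeds any peak threshold. (`adjacent_only = FALSE` restores the
overlap-only rule for comparison.)

Merged events pass a dual threshold — peak z above 3 and duration of at
least 4 cycles of the dominant frequency (the center of the member band
with the highest z) — followed by cycle verification: at least one complete
oscillation of the dominant-band waveform (two consecutive same-direction
zero crossings) must lie entirely inside the z > 3 region. This suppresses
envelope excursions produced by filter ringing on non-oscillatory
transients. Finally, a frequency-span k-means (k = 2, 10 restarts, fixed
seed) labels the larger-span cluster "spectrally diffuse" and rejects it.
Events with dominant frequency above 600 Hz are excluded from analysis by
default (`max_analysis_freq`).

Two properties of this detector are worth stating plainly, because they
shape what validation can and cannot claim:

* **Narrow-band noise is locally oscillatory.** After a constant-Q
  narrow-band filter, Gaussian noise looks like a slowly amplitude-modulated
  sinusoid; its z > 3 excursions last several cycles (median ~6 cycles of
  the band center in our measurements). Cycle-count criteria therefore
  cannot drive the false-alarm rate on featureless noise to zero: an
  envelope-z detector at z = 3 fires at order 1 event/s/channel on pure
  1/f noise, comparable to the baseline rates observed in real recordings.
  Detector validation consequently uses *template-matched* recovery: a
  planted burst counts as found only if an event on the right channel has
  its peak within 20 ms and its dominant frequency inside the burst's
  spectral main lobe, and the false-alarm reference is the number of such
  template matches on a burst-free rendering of the same noise.
* **Narrow filters smear short bursts.** A 6-cycle, 50 ms burst has a
  spectral main lobe of width about twice `frequency / n_cycles` (~40 Hz at
  120 Hz); an 8 Hz-wide analysis band passes only a slice of it, spread
  over the ~125 ms response time of the filter. The dominant band of a
  detected burst therefore wobbles among the 3-4 bands covered by the main
  lobe, and burst amplitudes quoted "relative to noise" are referenced to
  the band-limited noise floor of the full 60-800 Hz analysis range, not to
  a single narrow band.

## 2. Coincidence analysis

Detected events are reduced to points at their peak time. For each task
event (countdown digit, word onset, distractor onset, recall-vocalization
onset) a binary channels-by-bins raster is built with 10 ms bins over a
±1.5 s window (300 bins, half-open intervals; trials closer than 1.5 s to a
recording edge are dropped rather than padded). A spike at channel *i*, bin
*t* is a *co-HFO* iff any other channel has a spike within ±5 bins (±50
ms); each channel-bin is counted at most once.

Channels are classified by their maximum off-diagonal Pearson correlation
over the trial-concatenated rasters: correlated if that score exceeds
r* = 0.5 (sensitivity settings 0.3 and 0.7 are a parameter away), ties in
the score ordering broken by channel label so outputs are reproducible.
Classification is recomputed per alignment/phase by default. Per-bin
co-HFO counts are averaged within subject across trials, then across
subjects; the per-second display vector is the per-bin rate times
1/bin_width (×100 for 10 ms bins), and the probability vector is that
vector normalized to sum to one. Because normalization absorbs any constant
factor, the order of scaling and normalizing is immaterial; both vectors
are returned explicitly.

## 3. Sequence clustering, surrogates and stability

Co-bursting structure is clustered from the correlation-distance matrix
(1 − r over binarized channel series; constant channels are flagged and
placed at distance 1) by unweighted average-linkage (UPGMA) agglomeration
via `stats::hclust`. Flat labels come from a cluster-count cut; when no
count is given, k in 2..min(10, n−1) maximizing the mean silhouette width
is used — the cut rule is a free choice here, and silhouette is a
conventional, scale-free default.

The temporal-jitter surrogate shifts each event's peak time by an
independent draw — magnitude uniform on [50, 100] ms, sign equiprobable
(the symmetric-uniform alternative is available behind a flag) — reflecting
at the recording boundaries and preserving per-channel event counts
exactly. The synchrony index is the mean pairwise Pearson correlation of
the binarized channel series (zero-variance pairs excluded); it can be
slightly negative for anticorrelated series and is reported unclipped.

Bootstrap stability asks whether the session-level channel modules survive
resampling at the single-word level: original labels come from clustering
the trial-concatenated raster; each replicate resamples channels with
replacement within one word's raster, reclusters, and scores agreement
with the original labels by the Adjusted Rand Index over the replicate's
unique channels (duplicates agree by construction); replicate ARIs are
averaged per word, then across words. The per-word design is what gives
the procedure a meaningful null: reclustering the very data that defined
the original labels reproduces even arbitrary 2-cuts of noise (ARI
0.2-0.5 in our measurements), whereas per-word rasters of unstructured
bursting recluster near chance (|ARI| < 0.1).

## 4. Inference

The per-bin mixed model is `value ~ condition + (1 | subject)`, fitted
independently at each 10 ms bin, with the omnibus condition Wald F and
pairwise contrasts obtained by rotating the condition reference level;
Benjamini-Hochberg FDR correction is applied across the bins of each
contrast (not pooled across contrasts). For the balanced
one-observation-per-cell design the REML solution is available in closed
form — off the variance boundary the Wald F equals the classic
within-subject ANOVA ratio MS~condition~/MS~error~ with Satterthwaite
denominator df (s−1)(c−1); when the between-subject mean square drops below
the error mean square the REML subject variance truncates to zero and the
model collapses to OLS with residual df n−c. `per_bin_lmm()` uses this
closed form for balanced designs (the test suite asserts equality with the
lme4 route to ~1e-8 in both branches) and lme4 REML fits, templated with
`refit()` across bins, otherwise; a single-subject design falls back to a
fixed-effects fit, flagged. Under a null simulation (20 subjects, 4
conditions, 300 bins) the omnibus p-values are uniform
(Kolmogorov-Smirnov), and a planted 3-residual-SD condition effect in bins
140-160 is recovered after FDR.

The surrounding tests delegate to the standard routines: Shapiro-Wilk
gates the test family at α = 0.05 (n < 3 or constant samples go
nonparametric, flagged), one-way ANOVA or Kruskal-Wallis with Tukey HSD
follow-ups, paired/independent t or Wilcoxon, chi-squared for categorical
tables, Cohen's d with the normal-approximation CI (avoiding noncentral-t
iteration), and a max-statistic label-permutation test for FWER control
across a statistic map.

## 5. The synthetic LFP generator

The generator is the package's study population: every acceptance-style
claim is a parameter-recovery statement about data it produced. It
emulates:

* **Background**: Gaussian noise spectrally shaped to 1/f^α (inverse-FFT
  method; exact spectral control in O(n log n)), α = 1 and RMS 10 µV by
  default, at fs = 5000 Hz.
* **Bursts**: sinusoids of ≥4 cycles under a raised-cosine (Hann)
  envelope — the smooth onset/offset avoids injecting the very filter
  ringing the detector guards against — with log-uniform peak frequency
  (80-200 Hz default) and additive superposition on the noise; the
  with-bursts and without-bursts renderings of the same seed differ by
  exactly the sum of injected waveforms.
* **Task schedule**: per list, a 5 s countdown of five digits, twelve
  1.5 s words with 1.0 s inter-stimulus intervals, a 20 s arithmetic
  distractor block (five equation events; real pacing is self-paced and
  unreported, so even 4 s spacing is used), and a 30 s free-recall block.
  Words are flagged recalled with probability 0.3 (matching typical ~30%
  free-recall accuracy); vocalization onsets are drawn uniformly within
  the block with a minimum separation of 1.5 s — the real inter-recall
  interval distribution is unreported, so this is a stand-in, not an
  estimate. A paired-associate variant presents six pairs and emits cue
  events, with vocalization 1 s after each cue.
* **Rate modulation**: an inhomogeneous Poisson process (thinning) with
  baseline 0.8 bursts/s/channel — the typical high-gamma/ripple background
  rate — multiplied by a Gaussian peak at each recall onset (SD 50 ms,
  emulating the sharp vocalization-locked peak), a Gaussian dip centered
  1 s before recall (SD 150 ms), and a gain during the display of
  subsequently recalled words (a planted subsequent-memory effect).
* **Co-bursting groups**: a shared group point process carries
  `group_share = 0.9` of each member's baseline rate; members realize each
  group event with probability 0.95 at the shared time plus 2 ms Gaussian
  jitter, and an independent background process tops each channel back up
  to the baseline rate. Millisecond-scale jitter is deliberate: co-bursts
  must survive 10 ms binning (they land in the same or adjacent bins, so
  member correlations reach r ≈ 0.6-0.8 and form the r > 0.5 correlated
  class), mirroring the empirical finding that jittering timestamps by
  50-100 ms destroys the synchrony. One RNG substream is derived per
  subject from the master seed, so subjects are reproducible in isolation.

What the generator does *not* emulate — epileptiform spikes, line noise,
sleep stages, electrode drift, volume conduction, vocalization audio —
bounds what passing tests show: they validate the estimators and the
pipeline's wiring on clean, stationary data with known truth, not
robustness to the artifact structure of clinical recordings (the
specificity filter is exercised on planted two-population span data, which
is the situation it exists for).

## 6. Validation problem sizes and numerical choices

Detector recovery uses 50 bursts (120 Hz, 6 cycles, 6× the 60-800 Hz
noise-floor RMS) across 8 channels and 120 s at fs 5000. Temporal-profile
recovery uses 5 subjects × 20 lists (~360 recall trials): each co-bursting
group event contributes ~8 flagged channel-bins to one 10 ms bin, so
per-bin trial-mean rates are Poisson in the number of group events with
per-trial-bin mean ~0.007; at N trials the chance that some baseline bin
reaches the 4× peak level is roughly 300 · P(Pois(0.007N) ≥ 4·0.007N) —
about 4 expected stray bins at N ≈ 130, falling below 0.01 at N ≈ 360,
which is what makes the ±5-bin argmax localization reliable. Null
calibration of the per-bin model runs 200 replicates of the
20-subject × 4-condition × 300-bin design.

Other numerical choices, gathered in one place: all event times are seconds
from recording start with half-open `[onset, offset)` intervals; raster bin
*b* (1-based) covers `[-1.5 + (b-1)·0.01, -1.5 + b·0.01)`, so time zero is
the boundary between bins 150 and 151; k-means uses 10 restarts under a
fixed seed with squared-Euclidean distance on the 1-D spans and deterministic
larger-centroid rejection; correlation ties in channel sorting break
lexicographically; the sliding z-window shrinks at edges rather than
padding; all reported p-values are two-sided; and every significance call
in pipeline outputs names its procedure and threshold.

## 7. Known limitations

* The detector's absolute false-alarm rate on featureless noise is a
  property of the envelope-z design at z = 3, not of this implementation;
  analyses should treat absolute event counts as detector-relative.
* The closed-form LMM path covers the balanced one-observation-per-cell
  design only; severely unbalanced designs use the slower lme4 route with
  lmerTest Satterthwaite df.
* The k = 2 span filter assumes a genuinely two-population span mixture; on
  single-population data it must reject something, so parameter-recovery
  benchmarks run with it disabled.
* Anatomical analyses consume a channel table with region labels already
  assigned; no imaging or atlas handling is attempted, and the bundled
  region-to-lobe map covers common labels only.
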