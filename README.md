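# cohfo

Coincident high-frequency-oscillation (HFO) burst analysis for
intracranial EEG recorded during verbal memory tasks.

HFOs are transient oscillatory bursts (60–500 Hz, at least four cycles) in
the local field potential, generated by brief coordinated firing of local
neuronal assemblies. During memory encoding and recall, bursts on widely
separated cortical contacts co-occur within ±50 ms (**co-HFOs**), and this
global co-bursting is modulated by the task: suppressed about a second
before recall vocalization, sharply peaked at its onset, and elevated
during the display of words that will later be recalled. `cohfo` is for
electrophysiologists who want to detect these bursts and quantify their
large-scale coordination.

The package implements, as tidyverse-style functions over event tables:

* **Burst detection** — 38-band logarithmically spaced zero-phase FIR
  filter bank (60–800 Hz), Hilbert amplitude envelope, sliding 10 s
  z-score, dual thresholds (candidate z > 2 for ≥ 3 cycles; peak z > 3 and
  ≥ 4 cycles at the dominant frequency), connected-blob merging across
  adjacent bands, cycle verification, and a frequency-span k-means
  specificity filter (`detect_hfos()`).
* **Coincidence analysis** — peri-event binary rasters (10 ms bins,
  ±1.5 s), co-HFO counting within ±5 bins, channel classification by
  maximum pairwise correlation (r\* = 0.5), and normalized co-HFO
  probability traces per condition and channel class (`build_raster()`,
  `count_cohfo()`, `cohfo_traces()`, `contrast_traces()`).
* **Sequence structure** — UPGMA clustering of the 1 − r distance matrix,
  temporal-jitter surrogates (±50–100 ms), a mean-pairwise-correlation
  synchrony index, and per-word bootstrap cluster stability scored by the
  Adjusted Rand Index (`average_linkage_cluster()`, `jitter_surrogate()`,
  `synchrony()`, `bootstrap_stability()`).
* **Inference** — per-bin linear mixed models
  `value ~ condition + (1 | subject)` with Benjamini–Hochberg FDR across
  bins, normality-gated omnibus/post-hoc tests, Cohen's d, and
  max-statistic permutation FWER control (`per_bin_lmm()`, `fdr_bh()`,
  `omnibus_and_posthoc()`, `permutation_fwer()`).
* **Anatomy** — region-to-lobe mapping, correlated-pair Euclidean
  distances, lobe-wise proportions, per-channel word engagement
  (`assign_lobes()`, `pair_distances()`, `lobe_proportions()`,
  `engagement_frequency()`).
* **Synthetic LFP generator** — multichannel, multi-subject 1/f noise with
  injected bursts, millisecond-coincident channel groups, and a
  free-recall task schedule with recall-locked rate modulation, plus full
  ground truth for every injected burst (`sim_config()`,
  `simulate_dataset()`). Everything downstream is validated against it.

Results come back as tibbles; `autoplot()` methods cover rasters, traces
and clusterings, and `tidy()`/`glance()` methods cover fitted clusterings.

## Worked example

Simulate two subjects performing six free-recall lists, with co-bursting
on channels 1–4, a 4× rate peak at recall onset, and a 0.3× dip one second
earlier; then run the coincidence and clustering analyses on the known
ground-truth bursts:

```r
library(cohfo)
library(dplyr)

cfg <- sim_config(n_subjects = 2, n_channels = 8, n_lists = 6, seed = 42,
                  rate_profile = rate_profile(recall_peak_gain = 4,
                                              pre_recall_dip_gain = 0.3))
sim <- simulate_dataset(cfg, render_signal = FALSE)
events <- ground_truth_events(sim$ground_truth)
nrow(events)
#> [1] 7016

recalls <- filter(sim$task_events, trial_type == "RECALL")
tr <- cohfo_traces(events, recalls[, c("subject", "onset")],
                   t_max = cfg$duration)
head(attr(tr, "classification"), 4)
#> # A tibble: 4 × 5
#>   channel score  rank class      subject
#>   <chr>   <dbl> <int> <chr>      <chr>
#> 1 ch03    0.690     1 correlated S01
#> 2 ch04    0.690     2 correlated S01
#> 3 ch01    0.675     3 correlated S01
#> 4 ch02    0.650     4 correlated S01
```

The four co-bursting channels correlate at r ≈ 0.65–0.69 and form the
correlated class; the other four score near zero. The correlated-class
probability trace peaks at the recall-onset bin (−0.055 s here, i.e.
within ±6 bins of the vocalization onset at this modest trial count, with
peak probability 0.032 ≈ 10× the uniform 1/300):

```r
co <- filter(tibble::as_tibble(tr), channel_class == "correlated")
co$bin_center_s[which.max(co$probability)]
#> [1] -0.055
```

Clustering one subject's recall rasters recovers the planted module as a
single cluster, and jittering timestamps by 50–100 ms collapses the
synchrony index:

```r
rasters <- build_raster(filter(events, subject == "S01"),
                        filter(recalls, subject == "S01")$onset,
                        channels = sprintf("ch%02d", 1:8),
                        t_max = cfg$duration)
cl <- average_linkage_cluster(correlation_distance(rasters))
tidy(cl)          # channels 1-4 share cluster 1; channels 5-8 are singletons
bootstrap_stability(rasters, n_boot = 100, seed = 1)$ari_mean
#> [1] 0.598

jt <- jitter_surrogate(events, seed = 9, t_max = cfg$duration)
synchrony(rasters)                                     # 0.142
synchrony(build_raster(filter(jt, subject == "S01"),
                       filter(recalls, subject == "S01")$onset,
                       channels = sprintf("ch%02d", 1:8),
                       t_max = cfg$duration))          # 0.020
```

`run_pipeline(cfg, out_dir)` chains
simulate → detect → coincide → cluster → stats → anatomy and writes
tab-separated artifacts plus a JSON manifest (parameters, seeds, MD5 of
every output) sufficient to reproduce every byte.

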