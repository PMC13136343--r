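test_that("filter bank edges are log-spaced over the requested range", {
  bank <- make_filterbank(fs = 5000)
  expect_length(bank$edges, 39)
  expect_equal(bank$edges[1], 60)
  expect_equal(bank$edges[39], 800)
  expect_equal(diff(log(bank$edges)), rep(diff(log(c(60, 800))) / 38, 38),
               tolerance = 1e-12)
  expect_error(make_filterbank(fs = 1000, f_hi = 800),
               class = "cohfo_aliasing_error")
  expect_warning(bank2 <- make_filterbank(fs = 1000, f_hi = 800, reduce = TRUE))
  expect_equal(max(bank2$edges), 450)
})

test_that("band filters pass in-band tones, reject distant tones, at zero lag", {
  fs <- 2000
  bank <- make_filterbank(fs = fs, n_bands = 12, f_lo = 60, f_hi = 400)
  t <- seq(0, 6, by = 1 / fs)
  tone <- sin(2 * pi * 100 * t)
  b <- findInterval(100, bank$edges)
  mid <- round(length(t) / 3):round(2 * length(t) / 3)
  y <- filter_band(tone, bank, b)
  expect_gte(max(abs(y[mid])), 0.70)
  far <- findInterval(400 * 0.99, bank$edges)  # > 2 octaves above 100 Hz
  y2 <- filter_band(tone, bank, far)
  expect_lte(max(abs(y2[mid])), 0.10)
  cc <- stats::ccf(y[mid], tone[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("Hilbert envelope behaves as the analytic-signal magnitude", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  tone <- sin(2 * pi * 80 * t)
  env <- band_envelope(tone)
  mid <- 500:3500
  expect_true(all(abs(env[mid] - 1) < 0.02))
  expect_true(all(band_envelope(numeric(100)) == 0))
  expect_equal(band_envelope(3 * tone), 3 * env, tolerance = 1e-9)
  expect_error(band_envelope(c(1, NA, 2)))
})

test_that("sliding z-score matches its contracts", {
  fs <- 100
  expect_true(all(sliding_zscore(rep(5, 2000), fs, 10) == 0))
  set.seed(8)
  x <- rnorm(60000)
  z <- sliding_zscore(x, fs, 10)
  expect_gt(mean(z > 2), 0.018)
  expect_lt(mean(z > 2), 0.028)
  z2 <- sliding_zscore(x + 100, fs, 10)
  expect_equal(z, z2, tolerance = 1e-7, ignore_attr = TRUE)
  expect_error(sliding_zscore(rnorm(50), fs, 10))
})

test_that("candidate segmentation applies the cycle-duration rule", {
  fs <- 1000
  z <- numeric(2000)
  z[100:129] <- 3    # 0.030 s at 120 Hz: >= 3 cycles (0.025 s) -> kept
  z[500:519] <- 3    # 0.020 s -> rejected
  cand <- detect_candidates(z, 120, fs)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 100L)
  expect_equal(cand$end, 129L)
  expect_equal(nrow(detect_candidates(numeric(1000), 120, fs)), 0)
})

test_that("cross-band merging unions connected blobs and picks the dominant band", {
  cand <- tibble::tibble(
    band = c(5L, 6L), f_lo = c(100, 117), f_hi = c(117, 137),
    f_center = c(sqrt(100 * 117), sqrt(117 * 137)),
    start = c(100L, 110L), end = c(150L, 160L),
    peak_z = c(4, 5), peak_sample = c(120L, 130L), peak_amp = c(1, 2))
  ev <- merge_across_bands(cand)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$freq_min, 100)
  expect_equal(ev$freq_max, 137)
  expect_equal(ev$dominant_band, 6L)
  expect_equal(ev$peak_z, 5)
  expect_equal(ev$start, 100L)
  expect_equal(ev$end, 160L)

  # disjoint in time: stays separate
  cand2 <- cand
  cand2$start <- c(100L, 400L); cand2$end <- c(150L, 450L)
  expect_equal(nrow(merge_across_bands(cand2)), 2)

  # overlapping but two bands apart: merges only without the adjacency rule
  cand3 <- cand
  cand3$band <- c(5L, 9L)
  expect_equal(nrow(merge_across_bands(cand3)), 2)
  expect_equal(nrow(merge_across_bands(cand3, adjacent_only = FALSE)), 1)

  # single candidate: event mirrors it
  ev1 <- merge_across_bands(cand[1, ])
  expect_equal(ev1$freq_min, 100)
  expect_equal(ev1$freq_max, 117)
  expect_equal(ev1$n_members, 1L)
})

test_that("dual threshold enforces peak z and cycles at the dominant frequency", {
  fs <- 1000
  ev <- tibble::tibble(
    start = c(1L, 1L, 1L), end = c(40L, 40L, 20L),
    peak_z = c(3.5, 2.5, 5), dominant_band = 1L,
    dominant_freq = c(150, 150, 150), freq_min = 100, freq_max = 200,
    peak_sample = 10L, peak_amplitude = 1, n_members = 1L,
    members = list(1L, 1L, 1L))
  kept <- apply_dual_threshold(ev, fs)
  # 0.040 s >= 4/150 s with peak 3.5 kept; peak 2.5 rejected; 0.020 s rejected
  expect_equal(nrow(kept), 1)
  expect_equal(kept$peak_z, 3.5)
})

test_that("cycle verification separates oscillations from envelope transients", {
  fs <- 1000
  tt <- seq_len(200) / fs
  wave <- sin(2 * pi * 50 * tt)
  z <- rep(4, 200)
  expect_true(verify_cycles(wave, z))
  # above-threshold region shorter than one period
  z2 <- rep(0, 200); z2[100:110] <- 4
  expect_false(verify_cycles(wave, z2))
  # monophasic transient: no two same-direction zero crossings
  spike <- exp(-((seq_len(200) - 100) / 10)^2)
  expect_false(verify_cycles(spike, rep(4, 200)))
  expect_false(verify_cycles(wave[1:2], z[1:2]))
})

test_that("specificity filter separates planted narrow and wide span populations", {
  set.seed(13)
  ev <- tibble::tibble(freq_span = c(rnorm(60, 20, 3), rnorm(40, 300, 30)),
                       id = 1:100)
  out <- specificity_filter(ev, seed = 1)
  expect_equal(nrow(out$kept) + nrow(out$rejected), 100)
  expect_length(intersect(out$kept$id, out$rejected$id), 0)
  wide <- ev$id[ev$freq_span > 150]
  expect_gte(mean(wide %in% out$rejected$id), 0.95)
  expect_gte(mean(setdiff(ev$id, wide) %in% out$kept$id), 0.95)
  # deterministic under the seed
  out2 <- specificity_filter(ev, seed = 1)
  expect_identical(out$kept$id, out2$kept$id)
  # degenerate inputs pass through
  same <- tibble::tibble(freq_span = rep(10, 5))
  expect_warning(res <- specificity_filter(same))
  expect_equal(nrow(res$kept), 5)
  expect_equal(nrow(res$rejected), 0)
})
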