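test_that("pink noise has the requested spectral slope, RMS and length", {
  for (alpha in c(0, 1)) {
    cfg <- sim_config(n_channels = 1, fs = 1000, n_lists = 1, seed = 11,
                      noise_exponent = alpha, noise_rms = 7,
                      burst_freq_range = c(80, 200))
    x <- generate_pink_noise(cfg)$data[, 1]
    expect_length(x, 1000 * cfg$duration)
    expect_equal(sqrt(mean(x^2)), 7, tolerance = 1e-10)
    sp <- stats::spec.pgram(x, plot = FALSE, taper = 0)
    sel <- sp$freq > 0.01 & sp$freq < 0.4
    slope <- unname(coef(lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2])
    expect_lt(abs(slope - (-alpha)), 0.1)
  }
})

test_that("pink noise is bit-identical under a fixed seed", {
  cfg <- sim_config(n_channels = 2, fs = 500, n_lists = 1, seed = 4,
                    burst_freq_range = c(80, 200))
  expect_identical(generate_pink_noise(cfg)$data,
                   generate_pink_noise(cfg)$data)
})

test_that("burst waveforms have the right duration, peak and degenerate cases", {
  w <- make_burst_waveform(120, 6, 10, 5000)
  expect_length(w, round(5000 * 6 / 120))
  expect_equal(length(w) / 5000, 0.050)
  expect_lt(abs(max(abs(w)) - 10) / 10, 0.02)
  expect_true(all(make_burst_waveform(120, 6, 0, 5000) == 0))
  expect_error(make_burst_waveform(300, 4, 1, 500), class = "cohfo_aliasing_error")
})

test_that("task schedule follows the free-recall timing", {
  cfg <- sim_config(n_channels = 2, fs = 500, n_lists = 3, seed = 21,
                    burst_freq_range = c(80, 200))
  sch <- generate_task_schedule(cfg)
  words <- dplyr::filter(sch, trial_type == "WORD")
  expect_equal(nrow(words), 36)
  for (l in 1:3) {
    wl <- dplyr::filter(words, list == l)
    expect_equal(nrow(wl), 12)
    cd0 <- min(dplyr::filter(sch, list == l, trial_type == "COUNTDOWN")$onset)
    expect_equal(wl$onset[1] - cd0, 5.0)
    expect_equal(diff(wl$onset), rep(2.5, 11))
  }
  rec <- dplyr::filter(sch, trial_type == "RECALL")
  expect_true(all(rec$item %in% words$item[words$recalled]))
  expect_true(all(table(rec$list) <= 12))
  # vocalizations separated by >= 1.5 s within each recall block
  for (l in unique(rec$list)) {
    on <- sort(rec$onset[rec$list == l])
    if (length(on) > 1) expect_true(all(diff(on) >= 1.5 - 1e-9))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_channels = 0), class = "cohfo_invalid_config")
  expect_error(sim_config(fs = 300, burst_freq_range = c(80, 200)),
               class = "cohfo_invalid_config")
  expect_error(sim_config(duration = 10, n_lists = 1),
               class = "cohfo_invalid_config")
  expect_error(sim_config(burst_cycles = 2:3), class = "cohfo_invalid_config")
})

test_that("unmodulated simulation realizes the baseline rate within Poisson error", {
  cfg <- sim_config(n_subjects = 1, n_channels = 8, fs = 500, n_lists = 4,
                    seed = 31, burst_freq_range = c(80, 200))
  sim <- simulate_dataset(cfg, render_signal = FALSE)
  n <- nrow(sim$ground_truth)
  expected <- 0.8 * 8 * cfg$duration
  expect_lt(abs(n - expected), 3 * sqrt(expected))
})

test_that("degenerate group parameters behave as contracts say", {
  grp <- list(coincidence_group(1:4, jitter_sd = 0, participation_prob = 1))
  cfg <- sim_config(n_channels = 4, fs = 500, n_lists = 1, seed = 41,
                    coincidence_groups = grp,
                    burst_freq_range = c(80, 200))
  sim <- simulate_dataset(cfg, render_signal = FALSE)
  g <- dplyr::filter(sim$ground_truth, !is.na(group_id))
  # zero jitter + full participation: every group time appears once per member
  tab <- table(round(g$center_time, 9))
  expect_true(all(tab == 4))

  grp0 <- list(coincidence_group(1:4, participation_prob = 0))
  cfg0 <- sim_config(n_channels = 4, fs = 500, n_lists = 1, seed = 41,
                     coincidence_groups = grp0,
                     burst_freq_range = c(80, 200))
  sim0 <- simulate_dataset(cfg0, render_signal = FALSE)
  expect_equal(sum(!is.na(sim0$ground_truth$group_id)), 0)
})

test_that("injected bursts are exactly additive on the same noise seed", {
  cfg <- sim_config(n_subjects = 1, n_channels = 2, fs = 500, n_lists = 1,
                    seed = 51, burst_freq_range = c(80, 120),
                    rate_profile = rate_profile(baseline_rate = 0.1))
  with_b <- simulate_dataset(cfg, render_signal = TRUE, inject_bursts = TRUE)
  without <- simulate_dataset(cfg, render_signal = TRUE, inject_bursts = FALSE)
  expect_identical(with_b$ground_truth, without$ground_truth)
  diffsig <- with_b$signals[[1]]$data - without$signals[[1]]$data
  recon <- matrix(0, nrow(diffsig), ncol(diffsig))
  gt <- with_b$ground_truth
  for (i in seq_len(nrow(gt))) {
    w <- make_burst_waveform(gt$frequency[i], gt$n_cycles[i], gt$amplitude[i],
                             cfg$fs, phase = gt$phase[i])
    i0 <- round(gt$onset[i] * cfg$fs) + 1L
    idx <- i0:(i0 + length(w) - 1L)
    ok <- idx >= 1 & idx <= nrow(recon)
    recon[idx[ok], gt$channel[i]] <- recon[idx[ok], gt$channel[i]] + w[ok]
  }
  expect_equal(diffsig, recon, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("programmed rate profile is recovered from ground-truth burst times", {
  cfg <- sim_config(n_subjects = 2, n_channels = 8, fs = 500, n_lists = 8,
                    seed = 61,
                    rate_profile = rate_profile(recall_peak_gain = 4),
                    burst_freq_range = c(80, 200))
  sim <- simulate_dataset(cfg, render_signal = FALSE)
  rec <- dplyr::filter(sim$task_events, trial_type == "RECALL")
  rel <- unlist(lapply(seq_len(nrow(rec)), function(i) {
    gt <- sim$ground_truth[sim$ground_truth$subject == rec$subject[i], ]
    d <- gt$center_time - rec$onset[i]
    d[abs(d) < 0.5]
  }))
  expect_gt(length(rel), 200)
  near <- sum(abs(rel) < 0.1)   # within ~2 SD of the Gaussian peak
  far <- sum(abs(rel) > 0.3)
  # peak-gain 4 concentrates mass at the onset relative to flanks
  rate_near <- near / 0.2
  rate_far <- far / 0.4
  expect_gt(rate_near, 2 * rate_far)
})

test_that("ground-truth events reshape to the detector event schema", {
  cfg <- sim_config(n_channels = 4, fs = 500, n_lists = 1, seed = 71,
                    burst_freq_range = c(80, 200))
  sim <- simulate_dataset(cfg, render_signal = FALSE)
  ev <- ground_truth_events(sim$ground_truth)
  expect_true(all(c("subject", "channel", "onset", "offset", "peak_time",
                    "dominant_freq", "freq_span") %in% names(ev)))
  expect_true(all(ev$onset < ev$offset))
  expect_equal(nrow(ev), nrow(sim$ground_truth))
})
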