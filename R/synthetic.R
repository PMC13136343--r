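#' Task-locked burst rate profile
#'
#' Describes how the per-channel burst rate is modulated around the task
#' schedule: a multiplicative Gaussian peak at each recall-vocalization
#' onset, a multiplicative dip centered about one second before each recall
#' onset, and a gain during the on-screen display of subsequently recalled
#' words (a planted subsequent-memory effect).
#'
#' All times are seconds.
#'
#' @param baseline_rate Baseline burst rate, bursts/s/channel. Default 0.8,
#'   the typical high-gamma/ripple background rate in human iEEG.
#' @param recall_peak_gain Multiplicative rate factor at recall onset.
#' @param recall_peak_sd SD (s) of the Gaussian recall peak.
#' @param pre_recall_dip_gain Multiplicative factor (< 1 for a dip) centered
#'   at `pre_recall_dip_center` relative to recall onset.
#' @param pre_recall_dip_center Center of the dip relative to recall onset
#'   (s, negative = before).
#' @param pre_recall_dip_sd SD (s) of the Gaussian dip.
#' @param encode_gain Multiplicative factor during display of subsequently
#'   recalled words.
#'
#' @return A list of class `rate_profile`.
#' @export
rate_profile <- function(baseline_rate = 0.8,
                         recall_peak_gain = 1,
                         recall_peak_sd = 0.050,
                         pre_recall_dip_gain = 1,
                         pre_recall_dip_center = -1.0,
                         pre_recall_dip_sd = 0.150,
                         encode_gain = 1) {
  stopifnot(baseline_rate >= 0, recall_peak_gain >= 0,
            pre_recall_dip_gain >= 0, encode_gain >= 0,
            recall_peak_sd > 0, pre_recall_dip_sd > 0)
  structure(
    list(baseline_rate = baseline_rate,
         recall_peak_gain = recall_peak_gain,
         recall_peak_sd = recall_peak_sd,
         pre_recall_dip_gain = pre_recall_dip_gain,
         pre_recall_dip_center = pre_recall_dip_center,
         pre_recall_dip_sd = pre_recall_dip_sd,
         encode_gain = encode_gain),
    class = "rate_profile"
  )
}

#' Co-bursting channel group specification
#'
#' Members of a group draw bursts from a shared point process: each group
#' event is realized on each member with probability `participation_prob`,
#' at the shared time plus independent Gaussian jitter.
#'
#' @param members Integer channel indices (>= 2 distinct).
#' @param jitter_sd Timing spread (s) of members around the shared group
#'   time. Default 2 ms: genuine co-bursting is aligned at the
#'   millisecond scale (jittering by tens of ms destroys it).
#' @param participation_prob Probability that a member realizes a given
#'   group event.
#'
#' @return A list of class `coincidence_group`.
#' @export
coincidence_group <- function(members, jitter_sd = 0.002,
                              participation_prob = 1) {
  members <- as.integer(members)
  if (length(unique(members)) < 2L || anyDuplicated(members)) {
    abort("`members` must be >= 2 distinct channel indices.")
  }
  stopifnot(jitter_sd >= 0, participation_prob >= 0, participation_prob <= 1)
  structure(
    list(members = members, jitter_sd = jitter_sd,
         participation_prob = participation_prob),
    class = "coincidence_group"
  )
}

#' Simulation configuration
#'
#' Bundles everything the synthetic LFP generator needs: recording geometry,
#' 1/f background-noise parameters, the free-recall task schedule, burst
#' waveform parameters, co-bursting group structure, and the task-locked
#' rate profile.
#'
#' @param n_subjects Number of simulated subjects (>= 1).
#' @param n_channels Channels per subject (>= 1).
#' @param fs Sampling rate, Hz (default 5000).
#' @param duration Recording length, s. Defaults to the task-schedule length
#'   plus a 2 s pad at each end.
#' @param noise_exponent Spectral exponent alpha of the 1/f^alpha background.
#' @param noise_rms Background noise RMS, uV.
#' @param n_lists Number of word lists in the free-recall schedule.
#' @param seed Master RNG seed; one independent substream is derived per
#'   subject.
#' @param coincidence_groups List of [coincidence_group()] specs. Default: a
#'   single group over the first half of the channels (2 ms jitter,
#'   participation 0.95). `NULL` for none.
#' @param rate_profile A [rate_profile()].
#' @param group_share Fraction of each member channel's baseline rate routed
#'   through its shared group process (remainder is independent background).
#' @param recall_prob Probability a word is flagged as subsequently recalled.
#' @param burst_freq_range Burst peak-frequency range, Hz (log-uniform draw).
#' @param burst_cycles Integer vector of admissible cycle counts (>= 4).
#' @param burst_amplitude Peak envelope amplitude of injected bursts, uV.
#' @param task `"fr"` (free recall) or `"pal"` (cued recall with cue events).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1, n_channels = 8, fs = 5000,
                       duration = NULL, noise_exponent = 1, noise_rms = 10,
                       n_lists = 3, seed = 1,
                       coincidence_groups = "default",
                       rate_profile = cohfo::rate_profile(),
                       group_share = 0.9, recall_prob = 0.3,
                       burst_freq_range = c(80, 200),
                       burst_cycles = 4:8, burst_amplitude = 60,
                       task = c("fr", "pal")) {
  task <- match.arg(task)
  if (n_subjects < 1 || n_channels < 1 || n_lists < 1) {
    abort("All counts must be >= 1.", class = "cohfo_invalid_config")
  }
  if (fs <= 0) abort("`fs` must be positive.", class = "cohfo_invalid_config")
  if (fs < 2 * max(burst_freq_range)) {
    abort("`fs` must be at least twice the maximum burst frequency.",
          class = "cohfo_invalid_config")
  }
  if (any(burst_cycles < 4)) {
    abort("`burst_cycles` must all be >= 4.", class = "cohfo_invalid_config")
  }
  schedule_len <- 4 + n_lists * list_period(task)
  if (is.null(duration)) duration <- schedule_len
  if (duration <= 0) abort("`duration` must be positive.",
                           class = "cohfo_invalid_config")
  if (duration < schedule_len) {
    abort(sprintf("`duration` (%.1f s) is shorter than the task schedule (%.1f s).",
                  duration, schedule_len),
          class = "cohfo_invalid_config")
  }
  if (identical(coincidence_groups, "default")) {
    coincidence_groups <- if (n_channels >= 4) {
      list(coincidence_group(seq_len(ceiling(n_channels / 2)),
                             jitter_sd = 0.002, participation_prob = 0.95))
    } else {
      list()
    }
  }
  if (is.null(coincidence_groups)) coincidence_groups <- list()
  all_members <- unlist(lapply(coincidence_groups, `[[`, "members"))
  if (anyDuplicated(all_members)) {
    abort("Coincidence groups must have disjoint members.",
          class = "cohfo_invalid_config")
  }
  if (length(all_members) && max(all_members) > n_channels) {
    abort("Group member index exceeds `n_channels`.",
          class = "cohfo_invalid_config")
  }
  stopifnot(group_share >= 0, group_share <= 1,
            recall_prob >= 0, recall_prob <= 1)
  structure(
    list(n_subjects = n_subjects, n_channels = n_channels, fs = fs,
         duration = duration, noise_exponent = noise_exponent,
         noise_rms = noise_rms, n_lists = n_lists, seed = seed,
         coincidence_groups = coincidence_groups,
         rate_profile = rate_profile, group_share = group_share,
         recall_prob = recall_prob, burst_freq_range = burst_freq_range,
         burst_cycles = burst_cycles, burst_amplitude = burst_amplitude,
         task = task),
    class = "sim_config"
  )
}

# Fixed free-recall list timing: 5 s countdown, 12 words x (1.5 s display +
# 1.0 s ISI), 20 s distractor, 30 s recall, 5 s inter-list gap.
list_period <- function(task = "fr") {
  if (task == "pal") 5 + 6 * 2.5 + 20 + 30 + 5 else 5 + 12 * 2.5 + 20 + 30 + 5
}

subject_seeds <- function(config) {
  set.seed(config$seed)
  sample.int(.Machine$integer.max - 2L, config$n_subjects)
}

#' Generate 1/f^alpha background noise
#'
#' Synthesizes per-channel Gaussian noise spectrally shaped to a power
#' spectral density proportional to 1/f^alpha (inverse-FFT method), scaled
#' to an exact per-channel RMS. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @param subject Subject index (selects the per-subject RNG substream).
#'
#' @return An [lfp_record()].
#' @export
generate_pink_noise <- function(config, subject = 1) {
  stopifnot(inherits(config, "sim_config"))
  seed <- subject_seeds(config)[subject]
  set.seed(seed)
  n <- round(config$fs * config$duration)
  alpha <- config$noise_exponent
  freqs <- seq(0, n - 1) / n * config$fs
  # shaping weights on the two-sided FFT grid (mirror above Nyquist)
  f_fold <- pmin(freqs, config$fs - freqs)
  w <- c(0, f_fold[-1]^(-alpha / 2))
  data <- matrix(0, n, config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    x <- rnorm(n)
    y <- Re(fft(fft(x) * w, inverse = TRUE)) / n
    y <- y - mean(y)
    y <- y * config$noise_rms / sqrt(mean(y^2))
    data[, ch] <- y
  }
  colnames(data) <- sprintf("ch%02d", seq_len(config$n_channels))
  lfp_record(data, fs = config$fs, subject = sprintf("S%02d", subject))
}

#' Oscillatory burst waveform
#'
#' A sinusoid of `n_cycles` full cycles under a smooth envelope. The default
#' raised-cosine (Hann) envelope avoids sharp onsets/offsets that would ring
#' through band-pass filters. The carrier is phase-aligned so that (at
#' `phase = 0`) its crest coincides with the envelope maximum, making the
#' peak absolute sample value equal `amplitude` up to sampling granularity.
#'
#' @param frequency Carrier frequency, Hz (< fs/2).
#' @param n_cycles Number of full cycles (>= 1; detected HFOs require >= 4).
#' @param amplitude Peak envelope amplitude, uV.
#' @param fs Sampling rate, Hz.
#' @param envelope `"hann"` (raised cosine, default) or `"rect"`.
#' @param phase Carrier phase offset, radians.
#'
#' @return A numeric vector of `round(fs * n_cycles / frequency)` samples.
#' @export
make_burst_waveform <- function(frequency, n_cycles, amplitude, fs,
                                envelope = c("hann", "rect"), phase = 0) {
  envelope <- match.arg(envelope)
  if (frequency >= fs / 2) {
    abort(sprintf("Burst frequency %.1f Hz is not below Nyquist (%.1f Hz).",
                  frequency, fs / 2),
          class = "cohfo_aliasing_error")
  }
  n <- round(fs * n_cycles / frequency)
  t <- seq_len(n) - (n + 1) / 2 # centered sample times (in samples)
  env <- switch(envelope,
    hann = 0.5 * (1 + cos(2 * pi * t / n)),
    rect = rep(1, n)
  )
  amplitude * env * cos(2 * pi * frequency * t / fs + phase)
}

#' Free-recall task schedule
#'
#' Builds the timed event table of the emulated verbal memory task. Each
#' list runs: a 5 s countdown (five 1 s digits), twelve words displayed for
#' 1.5 s with a 1.0 s inter-stimulus interval, a 20 s arithmetic distractor
#' block, and a 30 s free-recall block in which vocalization onsets for the
#' subsequently recalled words are drawn uniformly with a minimum 1.5 s
#' separation. The `"pal"` variant presents six word pairs and emits CUE
#' events during recall, with vocalization 1 s after each cue.
#'
#' @param config A [sim_config()].
#' @param subject Subject index.
#'
#' @return A tibble with columns `onset`, `duration`, `trial_type`
#'   (COUNTDOWN/WORD/DISTRACTOR/RECALL/CUE), `item`, `recalled`, `list`,
#'   `subject`. Times are seconds from recording start.
#' @export
generate_task_schedule <- function(config, subject = 1) {
  stopifnot(inherits(config, "sim_config"))
  seed <- subject_seeds(config)[subject]
  set.seed(seed + 1L)
  pal <- config$task == "pal"
  n_words <- if (pal) 6L else 12L
  rows <- vector("list", config$n_lists)
  for (l in seq_len(config$n_lists)) {
    t0 <- 2 + (l - 1) * list_period(config$task)
    cd <- tibble(onset = t0 + 0:4, duration = 1,
                 trial_type = "COUNTDOWN", item = as.character(5:1),
                 recalled = NA, list = l)
    word_items <- sprintf("L%02dW%02d", l, seq_len(n_words))
    recalled <- runif(n_words) < config$recall_prob
    words <- tibble(onset = t0 + 5 + 2.5 * (seq_len(n_words) - 1),
                    duration = 1.5, trial_type = "WORD",
                    item = word_items, recalled = recalled, list = l)
    d0 <- t0 + 5 + 2.5 * n_words
    dist <- tibble(onset = d0 + 4 * (0:4), duration = 3,
                   trial_type = "DISTRACTOR",
                   item = sprintf("EQ%02d", 1:5), recalled = NA, list = l)
    r0 <- d0 + 20
    rec_items <- word_items[recalled]
    if (pal) {
      cues <- tibble(onset = r0 + 5 * (seq_len(n_words) - 1) + 0.5,
                     duration = 1.5, trial_type = "CUE",
                     item = word_items, recalled = recalled, list = l)
      voc <- tibble(onset = cues$onset[recalled] + 1.0, duration = 1,
                    trial_type = "RECALL", item = rec_items,
                    recalled = TRUE, list = l)
      rows[[l]] <- bind_rows(cd, words, dist, cues, voc)
    } else {
      voc_onsets <- draw_separated(length(rec_items),
                                   lo = r0 + 0.5, hi = r0 + 29.5,
                                   min_sep = 1.5)
      voc <- tibble(onset = voc_onsets, duration = 1,
                    trial_type = "RECALL", item = rec_items,
                    recalled = TRUE, list = l)
      rows[[l]] <- bind_rows(cd, words, dist, voc)
    }
  }
  out <- bind_rows(rows)
  if (max(out$onset + out$duration) > config$duration) {
    abort("Task schedule exceeds the recording duration.",
          class = "cohfo_invalid_config")
  }
  out$subject <- sprintf("S%02d", subject)
  arrange(out, .data$onset)
}

# Sorted uniform draws on [lo, hi] with a minimum separation; falls back to
# even spacing if rejection sampling keeps failing (overcrowded block).
draw_separated <- function(k, lo, hi, min_sep, max_tries = 200) {
  if (k == 0) return(numeric(0))
  for (i in seq_len(max_tries)) {
    x <- sort(runif(k, lo, hi))
    if (k == 1 || all(diff(x) >= min_sep)) return(x)
  }
  seq(lo, hi, length.out = k)
}

# Evaluate the task-locked multiplicative rate modulation at times t.
rate_modulation <- function(t, profile, task_events) {
  m <- rep(1, length(t))
  rec <- task_events$onset[task_events$trial_type == "RECALL"]
  if (length(rec)) {
    if (profile$recall_peak_gain != 1) {
      peak <- vapply(t, function(tt)
        max(exp(-(tt - rec)^2 / (2 * profile$recall_peak_sd^2))), 0)
      m <- m * (1 + (profile$recall_peak_gain - 1) * peak)
    }
    if (profile$pre_recall_dip_gain != 1) {
      ctr <- rec + profile$pre_recall_dip_center
      dip <- vapply(t, function(tt)
        max(exp(-(tt - ctr)^2 / (2 * profile$pre_recall_dip_sd^2))), 0)
      m <- m * (1 + (profile$pre_recall_dip_gain - 1) * dip)
    }
  }
  if (profile$encode_gain != 1) {
    words <- task_events[task_events$trial_type == "WORD" &
                           !is.na(task_events$recalled) &
                           task_events$recalled, , drop = FALSE]
    if (nrow(words)) {
      inside <- vapply(t, function(tt)
        any(tt >= words$onset & tt < words$onset + words$duration), FALSE)
      m[inside] <- m[inside] * profile$encode_gain
    }
  }
  m
}

# Inhomogeneous Poisson draw on [0, T] by thinning.
draw_inhomogeneous <- function(rate, modulation_fun, duration, lambda_max) {
  if (rate <= 0) return(numeric(0))
  n_cand <- rpois(1, lambda_max * duration)
  if (n_cand == 0) return(numeric(0))
  tt <- runif(n_cand, 0, duration)
  keep <- runif(n_cand) < rate * modulation_fun(tt) / lambda_max
  sort(tt[keep])
}

#' Simulate a multichannel, multi-subject dataset with known ground truth
#'
#' Draws burst times from an inhomogeneous Poisson process whose rate is the
#' baseline modulated by the task-locked [rate_profile()]; co-bursting
#' groups share event times (members participate with the configured
#' probability, at the shared time plus Gaussian jitter); the remaining rate
#' is realized as independent background bursts so the per-channel total
#' stays at `baseline_rate`. Optionally renders the full LFP by injecting
#' each burst waveform into 1/f background noise.
#'
#' @param config A [sim_config()].
#' @param render_signal If `FALSE`, skip waveform synthesis (events only) —
#'   sufficient for all raster/coincidence/clustering analyses.
#' @param inject_bursts If `FALSE`, render the background noise without the
#'   bursts (same noise realization as with bursts; their difference is
#'   exactly the sum of injected waveforms).
#'
#' @return A list with elements `signals` (list of [lfp_record()] per
#'   subject, or `NULL`), `task_events` (tibble), `ground_truth` (tibble of
#'   every injected burst: subject, channel, group_id, center_time, onset,
#'   offset, frequency, n_cycles, amplitude, phase), and `config`.
#' @export
simulate_dataset <- function(config, render_signal = TRUE,
                             inject_bursts = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- subject_seeds(config)
  prof <- config$rate_profile
  all_events <- vector("list", config$n_subjects)
  all_truth <- vector("list", config$n_subjects)
  signals <- if (render_signal) vector("list", config$n_subjects) else NULL

  for (s in seq_len(config$n_subjects)) {
    task_events <- generate_task_schedule(config, s)
    set.seed(seeds[s] + 2L)
    lam_max <- max(prof$recall_peak_gain, 1) * max(prof$encode_gain, 1) *
      max(prof$pre_recall_dip_gain, 1)
    modf <- function(tt) rate_modulation(tt, prof, task_events)
    groups <- config$coincidence_groups
    grouped <- if (length(groups)) unlist(lapply(groups, `[[`, "members")) else integer(0)
    ch_vec <- integer(0); ct_vec <- numeric(0); gid_vec <- integer(0)
    for (g in seq_along(groups)) {
      gr <- groups[[g]]
      g_rate <- config$group_share * prof$baseline_rate
      g_times <- draw_inhomogeneous(g_rate, modf, config$duration,
                                    g_rate * lam_max)
      for (ch in gr$members) {
        part <- runif(length(g_times)) < gr$participation_prob
        ct <- g_times[part] + rnorm(sum(part), 0, gr$jitter_sd)
        ch_vec <- c(ch_vec, rep(ch, length(ct)))
        ct_vec <- c(ct_vec, ct)
        gid_vec <- c(gid_vec, rep(g, length(ct)))
      }
    }
    for (ch in seq_len(config$n_channels)) {
      ind_rate <- prof$baseline_rate
      if (ch %in% grouped) {
        gr <- groups[[which(vapply(groups, function(g) ch %in% g$members, FALSE))]]
        ind_rate <- ind_rate -
          config$group_share * prof$baseline_rate * gr$participation_prob
      }
      ind_rate <- max(ind_rate, 0)
      i_times <- draw_inhomogeneous(ind_rate, modf, config$duration,
                                    ind_rate * lam_max)
      ch_vec <- c(ch_vec, rep(ch, length(i_times)))
      ct_vec <- c(ct_vec, i_times)
      gid_vec <- c(gid_vec, rep(NA_integer_, length(i_times)))
    }
    truth <- draw_burst_rows(config, s, ch_vec, ct_vec, gid_vec)
    if (nrow(truth)) {
      truth <- filter(truth, .data$onset >= 0,
                      .data$offset <= config$duration)
      truth <- arrange(truth, .data$channel, .data$onset)
    }
    all_events[[s]] <- task_events
    all_truth[[s]] <- truth
    if (render_signal) {
      rec <- generate_pink_noise(config, s)
      if (inject_bursts && nrow(truth)) {
        for (i in seq_len(nrow(truth))) {
          w <- make_burst_waveform(truth$frequency[i], truth$n_cycles[i],
                                   truth$amplitude[i], config$fs,
                                   phase = truth$phase[i])
          i0 <- round(truth$onset[i] * config$fs) + 1L
          idx <- i0:(i0 + length(w) - 1L)
          ok <- idx >= 1L & idx <= nrow(rec$data)
          rec$data[idx[ok], truth$channel[i]] <-
            rec$data[idx[ok], truth$channel[i]] + w[ok]
        }
      }
      signals[[s]] <- rec
    }
  }
  list(signals = signals,
       task_events = bind_rows(all_events),
       ground_truth = bind_rows(all_truth),
       config = config)
}

draw_burst_rows <- function(config, subject, channels, center_times,
                            group_ids) {
  n <- length(center_times)
  fr <- config$burst_freq_range
  f <- exp(runif(n, log(fr[1]), log(fr[2])))
  nc <- if (length(config$burst_cycles) == 1L) rep(config$burst_cycles, n) else
    sample(config$burst_cycles, n, replace = TRUE)
  dur <- nc / f
  tibble(subject = rep(sprintf("S%02d", subject), n), channel = channels,
         group_id = group_ids, center_time = center_times,
         onset = center_times - dur / 2, offset = center_times + dur / 2,
         frequency = f, n_cycles = nc,
         amplitude = rep(config$burst_amplitude, n),
         envelope = rep("hann", n),
         phase = runif(n, 0, 2 * pi))
}

#' Ground-truth bursts as a detector-style event table
#'
#' Reshapes the simulator's ground-truth table into the column layout
#' produced by [detect_hfos()], so every downstream analysis (rasters,
#' coincidence, clustering) can run directly on the known injected bursts.
#'
#' @param ground_truth The `ground_truth` tibble from [simulate_dataset()].
#'
#' @return A tibble with the standard HFO event columns.
#' @export
ground_truth_events <- function(ground_truth) {
  mutate(
    tibble(
      subject = ground_truth$subject,
      channel = sprintf("ch%02d", ground_truth$channel),
      onset = ground_truth$onset,
      offset = ground_truth$offset,
      peak_time = ground_truth$center_time,
      dominant_freq = ground_truth$frequency,
      freq_min = ground_truth$frequency,
      freq_max = ground_truth$frequency,
      peak_z = NA_real_,
      peak_amplitude = ground_truth$amplitude
    ),
    freq_span = .data$freq_max - .data$freq_min
  )
}
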