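#' Bipolar re-referencing of adjacent contacts
#'
#' Derives one channel per adjacent contact pair (first minus second) to
#' enhance spatial specificity and suppress volume conduction. Pairs must
#' lie on the same electrode shaft (checked against the `group` column of
#' the channel metadata when present).
#'
#' @param signal An [lfp_record()].
#' @param montage Data frame with columns `a`, `b`: channel labels of each
#'   adjacent pair. If `NULL`, built automatically from consecutive contacts
#'   within each electrode `group` of the channel metadata.
#'
#' @return An [lfp_record()] of derived channels named `"A-B"`.
#' @export
bipolar_rereference <- function(signal, montage = NULL) {
  stopifnot(inherits(signal, "lfp_record"))
  labs <- channel_labels(signal)
  meta <- signal$channels
  if (is.null(montage)) {
    if (!"group" %in% names(meta)) {
      abort("No `montage` given and channel metadata has no `group` column.")
    }
    montage <- dplyr::bind_rows(lapply(split(meta$channel, meta$group), function(ch) {
      if (length(ch) < 2) return(NULL)
      tibble(a = ch[-length(ch)], b = ch[-1])
    }))
  }
  montage <- as_tibble(montage)
  if (!all(c("a", "b") %in% names(montage))) {
    abort("`montage` needs columns `a` and `b`.")
  }
  bad <- !(montage$a %in% labs) | !(montage$b %in% labs)
  if (any(bad)) abort("Montage refers to unknown channels.")
  if ("group" %in% names(meta)) {
    grp <- setNames(meta$group, meta$channel)
    cross <- grp[montage$a] != grp[montage$b]
    if (any(cross)) {
      abort(sprintf("Montage pairs cross electrode groups: %s",
                    paste(montage$a[cross], montage$b[cross],
                          sep = "-", collapse = ", ")),
            class = "cohfo_montage_error")
    }
  }
  out <- signal$data[, montage$a, drop = FALSE] -
    signal$data[, montage$b, drop = FALSE]
  colnames(out) <- paste(montage$a, montage$b, sep = "-")
  lfp_record(out, fs = signal$fs, subject = signal$subject,
             units = signal$units)
}

#' Detect HFO bursts in a multichannel recording
#'
#' Runs the full per-channel detection chain: log-spaced zero-phase FIR
#' filter bank, Hilbert amplitude envelope, sliding z-score (10 s windows),
#' liberal candidate segmentation (z > 2 for at least three cycles of the
#' band center frequency), cross-band merging of temporally overlapping
#' candidates, dual-threshold acceptance (peak z > 3 and at least four
#' cycles at the dominant frequency), cycle verification, and a
#' frequency-span specificity filter. Events with dominant frequency above
#' `params$max_analysis_freq` are excluded from the returned set.
#'
#' @param signal An [lfp_record()].
#' @param bank An [make_filterbank()] for `signal$fs`; built with defaults
#'   when `NULL`.
#' @param params [detector_params()].
#' @param specificity Apply [specificity_filter()] (default `TRUE`).
#' @param seed Seed for the specificity filter's k-means restarts.
#'
#' @return A tibble of events sorted by (channel, onset) with columns
#'   `subject`, `channel`, `onset`, `offset`, `peak_time`, `dominant_freq`,
#'   `freq_min`, `freq_max`, `freq_span`, `peak_z`, `peak_amplitude`.
#'   Times are seconds from recording start; intervals are half-open.
#' @export
detect_hfos <- function(signal, bank = NULL, params = detector_params(),
                        specificity = TRUE, seed = 1) {
  stopifnot(inherits(signal, "lfp_record"))
  fs <- signal$fs
  if (is.null(bank)) bank <- make_filterbank(fs = fs)
  if (duration_s(signal) < params$z_window) {
    abort("Recording shorter than the z-score window.")
  }
  n <- n_samples(signal)
  L <- length(bank$kernels[[1]])
  nfft <- stats::nextn(n + L, c(2, 3, 5))
  amul <- analytic_multiplier(nfft)
  nch <- n_channels(signal)
  labs <- channel_labels(signal)

  # spectra of all channels once; then per band one response + per channel
  # one inverse FFT for the analytic band signal
  X <- vector("list", nch)
  for (ch in seq_len(nch)) {
    X[[ch]] <- fft(c(signal$data[, ch], numeric(nfft - n)))
  }
  margin <- function(b) ceiling(1.5 * fs / bank$centers[b])
  cand_by_ch <- rep(list(list()), nch)
  for (b in seq_along(bank$kernels)) {
    A <- zero_phase_response(bank$kernels[[b]], nfft) * amul
    for (ch in seq_len(nch)) {
      za <- fft(X[[ch]] * A, inverse = TRUE)[seq_len(n)] / nfft
      env <- Mod(za)
      z <- sliding_zscore(env, fs, params$z_window)
      cands <- detect_candidates(z, bank$centers[b], fs, params)
      if (nrow(cands) == 0) next
      mg <- margin(b)
      segs <- lapply(seq_len(nrow(cands)), function(i) {
        lo <- max(1L, cands$start[i] - mg)
        hi <- min(n, cands$end[i] + mg)
        list(offset = lo, wave = Re(za[lo:hi]), z = z[lo:hi])
      })
      cands$band <- b
      cands$f_lo <- bank$edges[b]
      cands$f_hi <- bank$edges[b + 1]
      cands$f_center <- bank$centers[b]
      cands$peak_amp <- Mod(za[cands$peak_sample])
      cands$seg <- segs
      cand_by_ch[[ch]][[length(cand_by_ch[[ch]]) + 1L]] <- cands
    }
  }

  ev_rows <- list()
  for (ch in seq_len(nch)) {
    cands <- bind_rows(cand_by_ch[[ch]])
    if (nrow(cands) == 0) next
    ev <- merge_across_bands(cands)
    ev <- apply_dual_threshold(ev, fs, params)
    if (nrow(ev) == 0) next
    ok <- vapply(seq_len(nrow(ev)), function(i) {
      seg <- ev$dom_seg[[i]]
      verify_cycles(seg$wave, seg$z, params)
    }, logical(1))
    ev <- ev[ok, , drop = FALSE]
    if (nrow(ev) == 0) next
    ev_rows[[ch]] <- tibble(
      subject = signal$subject,
      channel = labs[ch],
      onset = (ev$start - 1L) / fs,
      offset = ev$end / fs,
      peak_time = (ev$peak_sample - 0.5) / fs,
      dominant_freq = ev$dominant_freq,
      freq_min = ev$freq_min,
      freq_max = ev$freq_max,
      freq_span = ev$freq_max - ev$freq_min,
      peak_z = ev$peak_z,
      peak_amplitude = ev$peak_amplitude
    )
  }
  events <- bind_rows(ev_rows)
  if (nrow(events) == 0) return(empty_events())
  events <- filter(events, .data$dominant_freq <= params$max_analysis_freq)
  if (specificity && nrow(events) >= 2) {
    events <- specificity_filter(events, seed = seed)$kept
  }
  arrange(events, .data$channel, .data$onset)
}

empty_events <- function() {
  tibble(subject = character(0), channel = character(0),
         onset = numeric(0), offset = numeric(0), peak_time = numeric(0),
         dominant_freq = numeric(0), freq_min = numeric(0),
         freq_max = numeric(0), freq_span = numeric(0),
         peak_z = numeric(0), peak_amplitude = numeric(0))
}
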