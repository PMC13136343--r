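#' Detector parameters
#'
#' Thresholds and window lengths of the dual-threshold burst detector.
#'
#' @param candidate_z Liberal candidate threshold, SD units (default 2).
#' @param peak_z Peak threshold an event must exceed, SD units (default 3).
#' @param candidate_min_cycles Minimum sustained oscillation cycles at the
#'   candidate stage (default 3), counted at the band center frequency.
#' @param event_min_cycles Minimum cycles at the event's dominant frequency
#'   (default 4).
#' @param z_window Sliding z-score window, s (default 10).
#' @param max_analysis_freq Events with dominant frequency above this (Hz)
#'   are excluded from the returned set (default 600; set `Inf` to keep all).
#'
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(candidate_z = 2, peak_z = 3,
                            candidate_min_cycles = 3, event_min_cycles = 4,
                            z_window = 10, max_analysis_freq = 600) {
  if (peak_z < candidate_z) abort("`peak_z` must be >= `candidate_z`.")
  if (event_min_cycles < candidate_min_cycles || candidate_min_cycles < 1) {
    abort("Need `event_min_cycles` >= `candidate_min_cycles` >= 1.")
  }
  if (z_window <= 0) abort("`z_window` must be positive.")
  structure(
    list(candidate_z = candidate_z, peak_z = peak_z,
         candidate_min_cycles = candidate_min_cycles,
         event_min_cycles = event_min_cycles, z_window = z_window,
         max_analysis_freq = max_analysis_freq),
    class = "detector_params"
  )
}

#' Logarithmically spaced zero-phase FIR filter bank
#'
#' Builds contiguous band-pass filters with logarithmically spaced edges
#' (39 edges spanning 60-800 Hz by default). Kernels are Hamming
#' windowed-sinc FIR filters whose order is set from the transition
#' bandwidth 1/`transition_width`; the -6 dB point falls at the band edges.
#' Filters are applied with exact zero phase (delay-compensated symmetric
#' kernel in the frequency domain).
#'
#' @param fs Sampling rate, Hz.
#' @param n_bands Number of bands (default 38).
#' @param f_lo,f_hi Frequency range, Hz (defaults 60 and 800).
#' @param transition_width Transition-band parameter, s (default 0.200,
#'   i.e. a 5 Hz transition bandwidth).
#' @param reduce If `f_hi >= fs/2`, clip the top edge to 0.45*fs with a
#'   warning (`TRUE`) or fail (`FALSE`, default).
#'
#' @return An object of class `hfo_filterbank` with elements `edges`
#'   (length `n_bands + 1`), `centers` (geometric band centers), `kernels`
#'   (list of FIR coefficient vectors), `fs`.
#' @export
make_filterbank <- function(fs, n_bands = 38, f_lo = 60, f_hi = 800,
                            transition_width = 0.200, reduce = FALSE) {
  if (n_bands < 2) abort("`n_bands` must be >= 2.")
  if (f_lo <= 0 || f_lo >= f_hi) abort("Need 0 < f_lo < f_hi.")
  if (f_hi >= fs / 2) {
    if (!reduce) {
      abort(sprintf("f_hi = %g Hz is not below Nyquist (%g Hz).", f_hi, fs / 2),
            class = "cohfo_aliasing_error")
    }
    f_hi <- 0.45 * fs
    warn(sprintf("Filter bank top edge reduced to %g Hz.", f_hi))
  }
  edges <- exp(seq(log(f_lo), log(f_hi), length.out = n_bands + 1))
  centers <- sqrt(edges[-1] * edges[-(n_bands + 1)])
  trans_bw <- 1 / transition_width
  ord <- 2 * ceiling(3.3 * fs / trans_bw / 2) # even order, type-I FIR
  kernels <- lapply(seq_len(n_bands), function(b) {
    signal::fir1(ord, c(edges[b], edges[b + 1]) / (fs / 2), type = "pass")
  })
  structure(
    list(edges = edges, centers = centers, kernels = kernels, fs = fs,
         order = ord, transition_width = transition_width),
    class = "hfo_filterbank"
  )
}

#' @export
print.hfo_filterbank <- function(x, ...) {
  cat(sprintf(
    "<hfo_filterbank> %d bands, %.4g-%.4g Hz (log-spaced) @ fs %g Hz, FIR order %d\n",
    length(x$kernels), x$edges[1], x$edges[length(x$edges)], x$fs, x$order))
  invisible(x)
}

# Real zero-phase frequency response of a symmetric odd-length kernel on an
# nfft grid (delay compensation makes the response purely real).
zero_phase_response <- function(kernel, nfft) {
  L <- length(kernel)
  d <- (L - 1) / 2
  hp <- numeric(nfft)
  hp[seq_len(L)] <- kernel
  k <- seq(0, nfft - 1)
  Re(fft(hp) * exp(2i * pi * k * d / nfft))
}

# Multiplier turning a real spectrum into the analytic-signal spectrum.
analytic_multiplier <- function(nfft) {
  m <- numeric(nfft)
  m[1] <- 1
  if (nfft %% 2 == 0) {
    m[nfft / 2 + 1] <- 1
    m[2:(nfft / 2)] <- 2
  } else {
    m[2:((nfft + 1) / 2)] <- 2
  }
  m
}

#' Zero-phase band-pass filtering
#'
#' Applies one filter-bank band to a signal with exact zero phase via FFT
#' convolution of the delay-compensated symmetric kernel.
#'
#' @param x Numeric signal vector.
#' @param bank An [make_filterbank()] object.
#' @param band Band index.
#'
#' @return Filtered signal, same length as `x`.
#' @export
filter_band <- function(x, bank, band) {
  stopifnot(inherits(bank, "hfo_filterbank"))
  L <- length(bank$kernels[[band]])
  nfft <- stats::nextn(length(x) + L, c(2, 3, 5))
  A <- zero_phase_response(bank$kernels[[band]], nfft)
  X <- fft(c(x, numeric(nfft - length(x))))
  Re(fft(X * A, inverse = TRUE) / nfft)[seq_along(x)]
}

#' Hilbert amplitude envelope
#'
#' Instantaneous amplitude of a (band-limited) signal: the magnitude of its
#' analytic signal, computed via the FFT-based Hilbert transform.
#'
#' @param band_signal Numeric vector of finite samples.
#'
#' @return Nonnegative envelope, same length as the input.
#' @export
band_envelope <- function(band_signal) {
  if (!all(is.finite(band_signal))) abort("Input must be finite.")
  n <- length(band_signal)
  nfft <- stats::nextn(n, c(2, 3, 5))
  X <- fft(c(band_signal, numeric(nfft - n)))
  z <- fft(X * analytic_multiplier(nfft), inverse = TRUE) / nfft
  Mod(z)[seq_len(n)]
}

#' Sliding z-score
#'
#' Per-sample z-score of a series against the mean and SD of a centered
#' window (default 10 s); windows shrink (truncate) at the recording edges.
#' Samples with zero local SD get z = 0, flagged via the
#' `"zero_sd_samples"` attribute.
#'
#' @param envelope Numeric series.
#' @param fs Sampling rate, Hz.
#' @param z_window Window length, s.
#'
#' @return Numeric z series, same length.
#' @export
sliding_zscore <- function(envelope, fs, z_window = 10) {
  n <- length(envelope)
  w <- round(z_window * fs)
  if (n < w) abort("Series shorter than the z-score window.")
  half <- floor(w / 2)
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  cs <- cumsum(envelope)
  cs2 <- cumsum(envelope^2)
  s1 <- cs[hi] - c(0, cs)[lo]
  s2 <- cs2[hi] - c(0, cs2)[lo]
  m <- hi - lo + 1
  mu <- s1 / m
  v <- pmax((s2 - s1^2 / m) / (m - 1), 0)
  sdv <- sqrt(v)
  z <- (envelope - mu) / sdv
  zero_sd <- sdv <= .Machine$double.eps * pmax(abs(mu), 1)
  z[zero_sd] <- 0
  attr(z, "zero_sd_samples") <- sum(zero_sd)
  z
}

#' Candidate burst segments in one band
#'
#' Maximal runs of the z-scored envelope above the liberal candidate
#' threshold, kept when they last at least `candidate_min_cycles` cycles of
#' the band center frequency.
#'
#' @param z Z-scored envelope series.
#' @param band_freq Band center frequency, Hz.
#' @param fs Sampling rate, Hz.
#' @param params [detector_params()].
#'
#' @return Tibble with `start`, `end` (sample indices, inclusive), `peak_z`,
#'   `peak_sample`.
#' @export
detect_candidates <- function(z, band_freq, fs, params = detector_params()) {
  above <- z > params$candidate_z
  if (!any(above)) {
    return(tibble(start = integer(0), end = integer(0),
                  peak_z = numeric(0), peak_sample = integer(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fs >= params$candidate_min_cycles / band_freq)
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) {
    return(tibble(start = integer(0), end = integer(0),
                  peak_z = numeric(0), peak_sample = integer(0)))
  }
  pk <- vapply(seq_along(starts), function(i) {
    j <- starts[i]:ends[i]
    j[which.max(z[j])]
  }, integer(1))
  tibble(start = as.integer(starts), end = as.integer(ends),
         peak_z = z[pk], peak_sample = as.integer(pk))
}

#' Merge temporally overlapping candidates across bands
#'
#' Candidates form one event when they are connected (transitively) in
#' time-frequency space: overlapping in time by at least one sample and
#' lying in the same or adjacent frequency bands, i.e. an event is a
#' connected blob of above-threshold bands. The event's frequency span is
#' the extreme band edges of its members; the dominant frequency is the
#' center of the member band with the highest peak z; onset/offset is the
#' union extent. Requiring band adjacency keeps independent narrow-band
#' fluctuations in distant bands from fusing into spurious broadband
#' events; set `adjacent_only = FALSE` to merge on temporal overlap alone.
#'
#' @param candidates Tibble of per-band candidates with columns `band`,
#'   `f_lo`, `f_hi`, `f_center`, `start`, `end`, `peak_z`, `peak_sample`,
#'   `peak_amp` (and optionally segment list-columns carried through).
#' @param adjacent_only Require band adjacency for merging (default `TRUE`).
#'
#' @return Tibble of merged events: `start`, `end`, `peak_z`,
#'   `dominant_band`, `dominant_freq`, `freq_min`, `freq_max`,
#'   `peak_sample`, `peak_amplitude`, `n_members`, and `members`
#'   (list-column of member row indices into the time-sorted candidate
#'   table, which is attached as the `"candidates"` attribute). When the
#'   input carries a `seg` list-column, the dominant member's segment is
#'   exposed as `dom_seg`.
#' @export
merge_across_bands <- function(candidates, adjacent_only = TRUE) {
  empty <- tibble(start = integer(0), end = integer(0), peak_z = numeric(0),
                  dominant_band = integer(0), dominant_freq = numeric(0),
                  freq_min = numeric(0), freq_max = numeric(0),
                  peak_sample = integer(0), peak_amplitude = numeric(0),
                  n_members = integer(0), members = list())
  if (nrow(candidates) == 0) return(empty)
  ord <- order(candidates$start, candidates$end)
  cand <- candidates[ord, , drop = FALSE]
  n <- nrow(cand)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && cand$start[j] <= cand$end[i]) {
      if (!adjacent_only || abs(cand$band[j] - cand$band[i]) <= 1L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
      j <- j + 1L
    }
  }
  grp <- vapply(seq_len(n), find, integer(1))
  idx_list <- unname(split(seq_len(n), grp))
  dom <- vapply(idx_list, function(i) i[which.max(cand$peak_z[i])], integer(1))
  out <- tibble(
    start = vapply(idx_list, function(i) min(cand$start[i]), integer(1)),
    end = vapply(idx_list, function(i) max(cand$end[i]), integer(1)),
    peak_z = cand$peak_z[dom],
    dominant_band = cand$band[dom],
    dominant_freq = cand$f_center[dom],
    freq_min = vapply(idx_list, function(i) min(cand$f_lo[i]), numeric(1)),
    freq_max = vapply(idx_list, function(i) max(cand$f_hi[i]), numeric(1)),
    peak_sample = cand$peak_sample[dom],
    peak_amplitude = if ("peak_amp" %in% names(cand)) cand$peak_amp[dom] else NA_real_,
    n_members = lengths(idx_list),
    members = idx_list
  )
  if ("seg" %in% names(cand)) out$dom_seg <- cand$seg[dom]
  attr(out, "candidates") <- cand
  out
}

#' Dual-threshold event acceptance
#'
#' Keeps merged events whose peak z exceeds `peak_z` and whose duration is
#' at least `event_min_cycles` cycles of the dominant frequency.
#'
#' @param events Merged events from [merge_across_bands()].
#' @param fs Sampling rate, Hz.
#' @param params [detector_params()].
#'
#' @return Filtered events tibble.
#' @export
apply_dual_threshold <- function(events, fs, params = detector_params()) {
  if (nrow(events) == 0) return(events)
  dur <- (events$end - events$start + 1L) / fs
  keep <- events$peak_z > params$peak_z &
    dur >= params$event_min_cycles / events$dominant_freq
  events[keep, , drop = FALSE]
}

#' Cycle verification of a single event
#'
#' Confirms that the dominant-band waveform contains at least one complete
#' oscillation cycle (two consecutive same-direction zero crossings of the
#' mean-subtracted band signal) lying entirely within the region where the
#' z-scored envelope exceeds the peak threshold. Guards against envelope
#' excursions produced by filter ringing on non-oscillatory transients.
#'
#' @param wave Dominant-band filtered waveform covering the event.
#' @param z Z-scored envelope over the same samples.
#' @param params [detector_params()].
#'
#' @return `TRUE` if a full cycle sits inside the above-threshold region.
#' @export
verify_cycles <- function(wave, z, params = detector_params()) {
  if (length(wave) < 3) return(FALSE)
  w <- wave - mean(wave)
  above <- z > params$peak_z
  if (!any(above)) return(FALSE)
  up <- which(w[-length(w)] < 0 & w[-1] >= 0)
  dn <- which(w[-length(w)] >= 0 & w[-1] < 0)
  has_cycle <- function(cr) {
    if (length(cr) < 2) return(FALSE)
    for (k in seq_len(length(cr) - 1)) {
      span <- cr[k]:(cr[k + 1] + 1L)
      if (all(above[span])) return(TRUE)
    }
    FALSE
  }
  has_cycle(up) || has_cycle(dn)
}

#' Frequency-span specificity filter
#'
#' Two-cluster k-means on the event frequency span; the cluster with the
#' larger mean span is labeled spectrally diffuse and rejected. With fewer
#' than two events or zero span variance the input passes through unchanged
#' with a warning.
#'
#' @param events HFO event tibble with a `freq_span` column.
#' @param seed RNG seed for the multi-start k-means (10 restarts).
#'
#' @return A list with tibbles `kept` and `rejected` (a disjoint partition
#'   of the input).
#' @export
specificity_filter <- function(events, seed = 1) {
  if (nrow(events) < 2 || stats::var(events$freq_span) == 0) {
    warn("Too few events or zero span variance: specificity filter passed through.")
    return(list(kept = events, rejected = events[0, , drop = FALSE]))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  km <- kmeans(events$freq_span, centers = 2, nstart = 10)
  diffuse <- which.max(km$centers)
  keep <- km$cluster != diffuse
  list(kept = events[keep, , drop = FALSE],
       rejected = events[!keep, , drop = FALSE])
}
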