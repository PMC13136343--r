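#' Peri-event burst raster
#'
#' Binary channels x bins matrix aligned to one task event: bin `b` of a
#' channel is 1 iff at least one event peak time falls in the half-open
#' interval `[t0 + (b - 1 - n/2) * bin_width, t0 + (b - n/2) * bin_width)`
#' where `t0` is the align time. With the defaults (10 ms bins, +/-1.5 s
#' window) there are 300 bins and an event exactly at the align time lands
#' in bin 151 (the first bin at or after time zero).
#'
#' @param events HFO event tibble (needs `channel`, `peak_time`).
#' @param align_times Numeric vector of align times (s), e.g. task-phase
#'   onsets.
#' @param bin_width Bin width, s (default 0.010).
#' @param window Half-window, s (default 1.5); the raster covers
#'   `[-window, +window)`.
#' @param channels Channel labels fixing row order (default: sorted unique
#'   labels in `events`).
#' @param t_max Recording length (s); align times closer than `window` to an
#'   edge are dropped (truncated trials are excluded from averaging).
#'
#' @return A list of `burst_raster` objects (binary matrix with attributes
#'   `bin_width`, `window`, `align_time`), one per retained align time.
#' @export
build_raster <- function(events, align_times, bin_width = 0.010,
                         window = 1.5, channels = NULL, t_max = Inf) {
  if (length(align_times) == 0) return(list())
  if (is.null(channels)) channels <- sort(unique(events$channel))
  keep <- align_times - window >= 0 & align_times + window <= t_max
  align_times <- align_times[keep]
  n_bins <- round(2 * window / bin_width)
  lapply(align_times, function(t0) {
    m <- matrix(0L, length(channels), n_bins,
                dimnames = list(channels, NULL))
    rel <- events$peak_time - t0
    inw <- rel >= -window & rel < window & events$channel %in% channels
    if (any(inw)) {
      bins <- floor((rel[inw] + window) / bin_width) + 1L
      bins <- pmin(bins, n_bins)
      m[cbind(match(events$channel[inw], channels), bins)] <- 1L
    }
    structure(m, class = c("burst_raster", "matrix"),
              bin_width = bin_width, window = window, align_time = t0)
  })
}

#' @export
print.burst_raster <- function(x, ...) {
  cat(sprintf("<burst_raster> %d channels x %d bins (%.0f ms bins, +/-%.2g s around t = %.3f s), %d spikes\n",
              nrow(x), ncol(x), attr(x, "bin_width") * 1000,
              attr(x, "window"), attr(x, "align_time"), sum(x)))
  invisible(x)
}

#' Bin centers of a raster (s, relative to the align time)
#' @param raster A `burst_raster` or compatible binary matrix.
#' @export
raster_bin_centers <- function(raster) {
  bw <- attr(raster, "bin_width") %||% 0.010
  w <- attr(raster, "window") %||% (ncol(raster) * bw / 2)
  seq_len(ncol(raster)) * bw - w - bw / 2
}

#' Count coincident HFOs per time bin
#'
#' An HFO in (channel i, bin t) is a co-HFO iff any other channel has an
#' HFO within `halfwidth_bins` bins of t (default +/-5 bins = +/-50 ms at
#' 10 ms resolution). Each flagged channel-bin is counted once; the per-bin
#' count is the number of co-HFO-flagged channel-bins at that bin.
#'
#' @param raster Binary channels x bins matrix.
#' @param halfwidth_bins Coincidence half-window in bins (default 5).
#'
#' @return Integer vector of per-bin co-HFO counts (length = n bins).
#' @export
count_cohfo <- function(raster, halfwidth_bins = 5) {
  raster <- (raster != 0) * 1L
  nb <- ncol(raster)
  if (nrow(raster) < 2) return(integer(nb))
  # per-channel window indicator: any spike within +/- halfwidth_bins
  wind <- t(apply(raster, 1, function(r) {
    cs <- cumsum(r)
    i <- seq_len(nb)
    lo <- pmax(1L, i - halfwidth_bins)
    hi <- pmin(nb, i + halfwidth_bins)
    (cs[hi] - c(0, cs)[lo]) > 0
  }))
  S <- colSums(wind)
  co <- raster * ((matrix(S, nrow(raster), nb, byrow = TRUE) - wind) >= 1)
  as.integer(colSums(co))
}

#' Per-channel-bin co-HFO flags
#'
#' Same coincidence rule as [count_cohfo()] but returning the full binary
#' flag matrix (used for word-engagement analyses).
#'
#' @inheritParams count_cohfo
#' @return Binary channels x bins matrix of co-HFO flags.
#' @export
cohfo_flags <- function(raster, halfwidth_bins = 5) {
  raster <- (raster != 0) * 1L
  nb <- ncol(raster)
  if (nrow(raster) < 2) return(raster * 0L)
  wind <- t(apply(raster, 1, function(r) {
    cs <- cumsum(r)
    i <- seq_len(nb)
    lo <- pmax(1L, i - halfwidth_bins)
    hi <- pmin(nb, i + halfwidth_bins)
    (cs[hi] - c(0, cs)[lo]) > 0
  }))
  S <- colSums(wind)
  raster * ((matrix(S, nrow(raster), nb, byrow = TRUE) - wind) >= 1)
}

#' Pairwise channel correlation of concatenated rasters
#'
#' Pearson correlation between channels of the trial-concatenated binarized
#' burst series. Zero-variance channels get r = 0 off-diagonal (flagged via
#' the `"constant_channels"` attribute).
#'
#' @param rasters A single raster matrix or a list of rasters (equal channel
#'   sets; concatenated along time).
#'
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlation <- function(rasters) {
  m <- concat_rasters(rasters)
  if (nrow(m) < 2) abort("Need >= 2 channels.")
  v <- apply(m, 1, stats::var)
  const <- v == 0
  r <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  if (sum(!const) >= 2) {
    r[!const, !const] <- stats::cor(t(m[!const, , drop = FALSE]))
  }
  diag(r) <- 1
  attr(r, "constant_channels") <- rownames(m)[const]
  r
}

concat_rasters <- function(rasters) {
  if (is.list(rasters) && !is.matrix(rasters)) {
    nc <- vapply(rasters, nrow, integer(1))
    if (length(unique(nc)) != 1) abort("Rasters have differing channel counts.")
    do.call(cbind, rasters)
  } else {
    rasters
  }
}

#' Classify channels by maximum pairwise correlation
#'
#' Each channel's score is its maximum off-diagonal correlation; channels
#' are sorted by score (descending, ties broken by label) and classified as
#' correlated when the score exceeds the threshold (default r > 0.5;
#' sensitivity reruns use 0.3 and 0.7).
#'
#' @param corr Correlation matrix from [pairwise_correlation()].
#' @param threshold Correlation threshold r* (default 0.5).
#'
#' @return A tibble with `channel`, `score`, `class`
#'   (`"correlated"`/`"non-correlated"`), `rank`, sorted by rank.
#' @export
classify_and_sort <- function(corr, threshold = 0.5) {
  d <- corr
  diag(d) <- -Inf
  score <- apply(d, 1, max)
  out <- tibble(channel = rownames(corr) %||% as.character(seq_len(nrow(corr))),
                score = unname(score))
  out <- arrange(out, desc(.data$score), .data$channel)
  mutate(out,
         rank = row_number(),
         class = ifelse(.data$score > threshold, "correlated", "non-correlated"))
}
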