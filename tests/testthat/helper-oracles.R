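# Independent brute-force oracles used to check the fast implementations.

# Exhaustive pair scan: for every spike (i, t), check all other channels'
# bins within +/- hw for a partner spike.
bf_cohfo_count <- function(raster, hw = 5) {
  C <- nrow(raster); B <- ncol(raster)
  out <- integer(B)
  for (i in seq_len(C)) {
    for (t in which(raster[i, ] == 1)) {
      found <- FALSE
      for (j in seq_len(C)) {
        if (j == i) next
        for (u in max(1, t - hw):min(B, t + hw)) {
          if (raster[j, u] == 1) { found <- TRUE; break }
        }
        if (found) break
      }
      if (found) out[t] <- out[t] + 1L
    }
  }
  out
}

# Step-by-step UPGMA: clusters merge at the smallest unweighted mean
# pairwise distance; returns merge heights and the member sets merged.
bf_upgma <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  merged_sets <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    new_set <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merged_sets[[length(merged_sets) + 1]] <- new_set
    clusters <- c(clusters[-best], list(new_set))
  }
  list(heights = heights, sets = merged_sets)
}

# hclust merge table -> list of member sets in merge order.
hclust_sets <- function(hc) {
  n <- nrow(hc$merge) + 1
  sets <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    members <- function(x) if (x < 0) -x else sets[[x]]
    sets[[k]] <- sort(c(members(hc$merge[k, 1]), members(hc$merge[k, 2])))
  }
  sets
}

# Pair-counting ARI from the four pair-category counts (independent of the
# contingency-table formula used by the implementation).
bf_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(if (n10 + n01 == 0) 1 else 0)
  2 * (n11 * n00 - n10 * n01) / denom
}

# Literal BH step-up: find the largest k with p_(k) <= k q / m.
bf_bh_mask <- function(p, q = 0.05) {
  m <- length(p)
  if (m == 0) return(logical(0))
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  mask <- logical(m)
  if (length(k)) mask[o[seq_len(max(k))]] <- TRUE
  mask
}

# Co-bursting raster: `prob` per-bin firing probability for a shared master
# train; members copy master spikes with small bin jitter.
make_cobursting_raster <- function(n_ch = 6, n_bins = 3000, prob = 0.02,
                                   jitter_bins = 0, seed = 1) {
  set.seed(seed)
  master <- which(runif(n_bins) < prob)
  m <- matrix(0L, n_ch, n_bins,
              dimnames = list(sprintf("ch%02d", seq_len(n_ch)), NULL))
  for (i in seq_len(n_ch)) {
    pos <- master + sample(-jitter_bins:jitter_bins, length(master),
                           replace = TRUE)
    pos <- pos[pos >= 1 & pos <= n_bins]
    m[i, pos] <- 1L
  }
  m
}

# Two-block raster: channels within a block share most spikes, blocks are
# independent.
make_block_raster <- function(n_per_block = 4, n_bins = 2000, prob = 0.03,
                              share = 0.9, seed = 1) {
  set.seed(seed)
  blocks <- lapply(1:2, function(b) {
    master <- which(runif(n_bins) < prob)
    t(vapply(seq_len(n_per_block), function(i) {
      keep <- master[runif(length(master)) < share]
      extra <- which(runif(n_bins) < prob * (1 - share))
      row <- integer(n_bins)
      row[unique(c(keep, extra))] <- 1L
      row
    }, integer(n_bins)))
  })
  m <- rbind(blocks[[1]], blocks[[2]])
  rownames(m) <- sprintf("ch%02d", seq_len(2 * n_per_block))
  m
}

# Raster -> event-table helper (bin centers as peak times).
raster_to_events <- function(m, bin_width = 0.010, subject = "s1") {
  idx <- which(m == 1, arr.ind = TRUE)
  tibble::tibble(subject = subject,
                 channel = rownames(m)[idx[, 1]],
                 peak_time = (idx[, 2] - 0.5) * bin_width)
}

# Small filter bank + noise record for detection unit tests (kept light).
small_detect_fixture <- function(seed = 3, n_channels = 1, fs = 2000) {
  cfg <- sim_config(n_channels = n_channels, fs = fs, n_lists = 1,
                    seed = seed, noise_rms = 10,
                    burst_freq_range = c(80, 200))
  list(config = cfg,
       noise = generate_pink_noise(cfg),
       bank = make_filterbank(fs = fs, n_bands = 12, f_lo = 60, f_hi = 400))
}

# Analysis-range noise floor (RMS of the background within the filter-bank
# range), the reference level for burst SNR.
analysis_band_rms <- function(x, fs, f_lo = 60, f_hi = 400) {
  bf <- signal::butter(4, c(f_lo, f_hi) / (fs / 2), "pass")
  sqrt(mean(signal::filtfilt(bf, x)^2))
}

inject_bursts <- function(record, channel, centers, freq, n_cycles, amp) {
  fs <- record$fs
  for (ct in centers) {
    w <- make_burst_waveform(freq, n_cycles, amp, fs)
    i0 <- round((ct - length(w) / 2 / fs) * fs) + 1L
    idx <- i0:(i0 + length(w) - 1L)
    record$data[idx, channel] <- record$data[idx, channel] + w
  }
  record
}
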