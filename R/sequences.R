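#' Correlation distance between channels
#'
#' One minus the pairwise Pearson correlation of the binarized burst series:
#' channels with similar burst timing are close (d near 0), anticorrelated
#' channels far (d near 2). Constant channels are flagged and assigned
#' distance 1 to every other channel (r = 0 convention).
#'
#' @param rasters A raster matrix or list of rasters (concatenated).
#'
#' @return A symmetric distance matrix (zero diagonal, values in [0, 2])
#'   with a `"constant_channels"` attribute.
#' @export
correlation_distance <- function(rasters) {
  r <- pairwise_correlation(rasters)
  d <- 1 - r
  diag(d) <- 0
  attr(d, "constant_channels") <- attr(r, "constant_channels")
  d
}

#' Average-linkage (UPGMA) clustering of co-bursting channels
#'
#' Agglomerative clustering of the correlation-distance matrix with
#' unweighted average linkage, delegated to [stats::hclust()]. Flat labels
#' come from a cluster-count cut: either a fixed `k`, or (default) the k in
#' 2..min(10, n-1) maximizing the mean silhouette width.
#'
#' @param dist_matrix Symmetric distance matrix (e.g.
#'   [correlation_distance()]).
#' @param k Number of flat clusters; `NULL` (default) selects k by mean
#'   silhouette.
#' @param h Alternatively, a merge-height cut.
#'
#' @return An object of class `cohfo_clust`: list with `hclust` (the merge
#'   tree), `labels` (named cluster id per channel), `leaf_order` (display
#'   ordering), `k`, `dist` (the input distances).
#' @export
average_linkage_cluster <- function(dist_matrix, k = NULL, h = NULL) {
  n <- nrow(dist_matrix)
  if (is.null(n) || n < 2) abort("Need >= 2 channels to cluster.")
  if (is.null(rownames(dist_matrix))) {
    rownames(dist_matrix) <- colnames(dist_matrix) <-
      sprintf("ch%02d", seq_len(n))
  }
  hc <- hclust(as.dist(dist_matrix), method = "average")
  if (!is.null(h)) {
    labels <- cutree(hc, h = h)
    k <- length(unique(labels))
  } else {
    if (is.null(k)) k <- pick_k_silhouette(hc, dist_matrix)
    labels <- cutree(hc, k = k)
  }
  structure(
    list(hclust = hc, labels = labels,
         leaf_order = hc$labels[hc$order], k = k, dist = dist_matrix),
    class = "cohfo_clust"
  )
}

pick_k_silhouette <- function(hc, dist_matrix) {
  n <- nrow(dist_matrix)
  ks <- 2:min(10, n - 1)
  if (length(ks) == 0 || ks[1] > max(ks)) return(2L)
  if (!requireNamespace("cluster", quietly = TRUE)) return(2L)
  sil <- vapply(ks, function(k) {
    lab <- cutree(hc, k = k)
    if (length(unique(lab)) < 2) return(-Inf)
    mean(cluster::silhouette(lab, stats::as.dist(dist_matrix))[, "sil_width"])
  }, numeric(1))
  ks[which.max(sil)]
}

#' @export
print.cohfo_clust <- function(x, ...) {
  cat(sprintf("<cohfo_clust> %d channels, UPGMA, %d flat clusters\n",
              length(x$labels), x$k))
  invisible(x)
}

#' @export
tidy.cohfo_clust <- function(x, ...) {
  tibble(channel = names(x$labels), cluster = unname(x$labels),
         leaf_position = match(names(x$labels), x$leaf_order))
}

#' @export
glance.cohfo_clust <- function(x, ...) {
  tibble(n_channels = length(x$labels), k = x$k,
         merge_height_max = max(x$hclust$height))
}

#' Serialize a cluster tree to Newick
#'
#' Branch lengths are derived from the UPGMA merge heights (ultrametric
#' tree: each leaf sits at depth height/2 of its cluster's merge).
#'
#' @param x A `cohfo_clust`.
#' @return A single Newick string (terminated by `;`).
#' @export
cluster_newick <- function(x) {
  hc <- x$hclust
  node_str <- function(i) {
    # i indexes the merge table rows; negative entries are leaves
    left <- hc$merge[i, 1]; right <- hc$merge[i, 2]
    h <- hc$height[i]
    part <- function(j) {
      if (j < 0) {
        sprintf("%s:%g", hc$labels[-j], h / 2)
      } else {
        sprintf("%s:%g", node_str(j), (h - hc$height[j]) / 2)
      }
    }
    sprintf("(%s,%s)", part(left), part(right))
  }
  paste0(node_str(nrow(hc$merge)), ";")
}

#' Temporal-jitter surrogate events
#'
#' Randomly perturbs every event's peak time by an independent shift whose
#' magnitude is uniform on [jitter_min, jitter_max] with equiprobable sign,
#' preserving per-channel event counts (and hence burst rates) while
#' destroying millisecond-scale coincidence. Shifts that would leave the
#' recording are reflected at the boundary.
#'
#' @param events HFO event tibble.
#' @param jitter_min,jitter_max Jitter magnitude bounds, s (defaults 0.050
#'   and 0.100).
#' @param t_max Recording length, s (reflection boundary).
#' @param seed Optional RNG seed.
#' @param symmetric If `TRUE`, draw shifts uniform on
#'   [-jitter_max, +jitter_max] instead (alternative reading of a
#'   "+/- 50-100 ms window").
#'
#' @return The events tibble with jittered `peak_time` (onset/offset shifted
#'   by the same amount).
#' @export
jitter_surrogate <- function(events, jitter_min = 0.050, jitter_max = 0.100,
                             t_max = Inf, seed = NULL, symmetric = FALSE) {
  if (jitter_min > jitter_max) abort("`jitter_min` must be <= `jitter_max`.")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(events)
  if (n == 0) return(events)
  shift <- if (symmetric) {
    runif(n, -jitter_max, jitter_max)
  } else {
    runif(n, jitter_min, jitter_max) * sample(c(-1, 1), n, replace = TRUE)
  }
  pt <- events$peak_time + shift
  pt <- ifelse(pt < 0, -pt, pt)
  pt <- ifelse(pt > t_max, 2 * t_max - pt, pt)
  out <- events
  applied <- pt - events$peak_time
  out$peak_time <- pt
  if ("onset" %in% names(out)) out$onset <- out$onset + applied
  if ("offset" %in% names(out)) out$offset <- out$offset + applied
  out
}

#' Synchrony index of a raster
#'
#' Mean pairwise Pearson correlation of the binarized channel series. Pairs
#' involving a zero-variance channel are excluded; with no valid pair the
#' result is `NA` with a `"no_valid_pairs"` attribute. Values can be
#' slightly negative for anticorrelated series and are reported unclipped.
#'
#' @param rasters A raster matrix or list of rasters (concatenated).
#'
#' @return A single unitless index.
#' @export
synchrony <- function(rasters) {
  m <- concat_rasters(rasters)
  if (nrow(m) < 2) abort("Need >= 2 channels.")
  v <- apply(m, 1, stats::var)
  ok <- v > 0
  if (sum(ok) < 2) {
    out <- NA_real_
    attr(out, "no_valid_pairs") <- TRUE
    return(out)
  }
  r <- stats::cor(t(m[ok, , drop = FALSE]))
  mean(r[upper.tri(r)])
}

#' Adjusted Rand Index between two partitions
#'
#' Pair-counting agreement between two labelings, adjusted for chance:
#' 1 for identical partitions, expected 0 under random labeling, down to
#' negative values for systematic disagreement. When either partition is a
#' single cluster (or all singletons matching), the chance adjustment makes
#' the index 0 by convention unless both are identical.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#'
#' @return A single numeric value in [-1, 1].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("Label vectors must have equal length.")
  }
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) {
    # degenerate partitions (e.g. all-one-cluster vs all-one-cluster)
    return(if (sum_ij == max_index) 1 else 0)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Bootstrap stability of channel clustering
#'
#' Quantifies whether the channel modules found in the full session survive
#' resampling at the single-word level. The original labels come from
#' clustering the trial-concatenated raster; then, for every trial (word)
#' and bootstrap replicate, channels are resampled with replacement, the
#' replicate's per-trial raster is reclustered, and agreement with the
#' original labels is scored by the Adjusted Rand Index restricted to the
#' unique channels present in the replicate (duplicate draws agree by
#' construction). Replicate ARIs are averaged per trial, then across
#' trials. Genuine modular structure reappears in individual words (high
#' ARI); unstructured bursting does not (ARI near zero).
#'
#' @param rasters A list of raster matrices (one per trial/word) with a
#'   common channel set, or a single matrix (treated as one trial; note the
#'   replicate then reuses the very data that defined the original labels,
#'   which inflates the null).
#' @param n_boot Bootstrap replicates per trial (default 100).
#' @param k Flat cluster count passed to [average_linkage_cluster()]
#'   (`NULL` = silhouette-selected, per fit).
#' @param seed RNG seed.
#'
#' @return A `stability_result` tibble: `ari_mean`, `ari_sd` (SD across
#'   trials, or across replicates for a single trial), `n_boot`,
#'   `n_trials`, plus per-trial replicate ARI values in the `"ari"`
#'   attribute.
#' @export
bootstrap_stability <- function(rasters, n_boot = 100, k = NULL, seed = 1) {
  if (is.matrix(rasters)) rasters <- list(rasters)
  pooled <- concat_rasters(rasters)
  if (nrow(pooled) < 3) abort("Need >= 3 channels for bootstrap stability.")
  set.seed(seed)
  labs0 <- average_linkage_cluster(correlation_distance(pooled), k = k)$labels
  per_trial <- lapply(rasters, function(m) {
    ari <- numeric(n_boot)
    for (i in seq_len(n_boot)) {
      repeat {
        idx <- sample(nrow(m), replace = TRUE)
        if (length(unique(idx)) >= 2) break
      }
      mb <- m[idx, , drop = FALSE]
      rownames(mb) <- sprintf("r%03d", seq_along(idx))
      db <- correlation_distance(mb)
      kb <- if (is.null(k)) NULL else min(k, length(unique(idx)))
      cb <- average_linkage_cluster(db, k = kb)
      first <- !duplicated(idx)
      uniq <- idx[first]
      ari[i] <- adjusted_rand_index(labs0[uniq],
                                    unname(cb$labels[first]))
    }
    ari
  })
  ari_all <- vapply(per_trial, mean, numeric(1))
  out <- tibble(ari_mean = mean(ari_all),
                ari_sd = if (length(rasters) > 1) sd(ari_all) else
                  sd(per_trial[[1]]),
                n_boot = n_boot, n_trials = length(rasters))
  attr(out, "ari") <- per_trial
  class(out) <- c("stability_result", class(out))
  out
}
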