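#' Default region-label to cortical-lobe map
#'
#' Covers common automated-anatomical-labeling style region names. The
#' limbic lobe comprises the hippocampus, amygdala, posterior cingulate and
#' parahippocampal cortex; everything else maps to its geometric lobe.
#' Extend or override by passing your own two-column table to
#' [assign_lobes()].
#'
#' @return Tibble with columns `region`, `lobe`.
#' @export
default_lobe_map <- function() {
  tibble(
    region = c(
      "Hippocampus", "Amygdala", "Posterior cingulate", "Cingulate gyrus posterior",
      "Parahippocampal gyrus", "Parahippocampal cortex",
      "Superior temporal gyrus", "Middle temporal gyrus",
      "Inferior temporal gyrus", "Temporal pole", "Fusiform gyrus",
      "Heschl gyrus",
      "Superior frontal gyrus", "Middle frontal gyrus",
      "Inferior frontal gyrus", "Precentral gyrus", "Orbitofrontal cortex",
      "Paracentral lobule", "Supplementary motor area", "Rectus gyrus",
      "Postcentral gyrus", "Superior parietal gyrus",
      "Inferior parietal gyrus", "Supramarginal gyrus", "Angular gyrus",
      "Precuneus",
      "Calcarine cortex", "Cuneus", "Lingual gyrus",
      "Superior occipital gyrus", "Middle occipital gyrus",
      "Inferior occipital gyrus"
    ),
    lobe = c(
      rep("limbic", 6),
      rep("temporal", 6),
      rep("frontal", 8),
      rep("parietal", 6),
      rep("occipital", 6)
    )
  )
}

#' Assign cortical lobes to channels
#'
#' Joins the channel table against a region-to-lobe map (case-insensitive
#' exact match on the region label). Channels with unmapped regions are
#' labeled `"unassigned"`, excluded from lobe-level analyses downstream,
#' and counted in the `"n_unassigned"` attribute.
#'
#' @param channel_table Tibble with at least `channel` and `region` columns
#'   (typically also `x`, `y`, `z` MNI mm, `group`, `tissue`).
#' @param lobe_map Two-column tibble `region`, `lobe`
#'   (default [default_lobe_map()]).
#'
#' @return The channel table with a `lobe` column.
#' @export
assign_lobes <- function(channel_table, lobe_map = default_lobe_map()) {
  channel_table <- as_tibble(channel_table)
  if (!"region" %in% names(channel_table)) {
    abort("Channel table must have a `region` column.")
  }
  key <- tolower(trimws(lobe_map$region))
  idx <- match(tolower(trimws(channel_table$region)), key)
  out <- mutate(channel_table,
                lobe = ifelse(is.na(idx), "unassigned", lobe_map$lobe[idx]))
  n_un <- sum(out$lobe == "unassigned")
  if (n_un > 0) {
    warn(sprintf("%d channel(s) with unmapped regions set to 'unassigned'.", n_un))
  }
  attr(out, "n_unassigned") <- n_un
  out
}

#' Euclidean distances between correlated channel pairs
#'
#' @param channel_table Channel table with `channel`, `x`, `y`, `z`
#'   (MNI mm).
#' @param pairs Tibble with columns `a`, `b`: channel labels of each
#'   correlated pair.
#' @param breaks Histogram bin edges in mm (default 10 mm bins, 0-200 mm).
#'
#' @return A list with `distances` (tibble `a`, `b`, `distance_mm`),
#'   `histogram` (tibble `bin_lo`, `bin_hi`, `count`), and
#'   `n_skipped` (pairs missing coordinates).
#' @export
pair_distances <- function(channel_table, pairs,
                           breaks = seq(0, 200, by = 10)) {
  stopifnot(all(c("a", "b") %in% names(pairs)))
  coords <- channel_table[, c("channel", "x", "y", "z")]
  pa <- left_join(pairs, coords, by = c(a = "channel"))
  pb <- left_join(pairs, coords, by = c(b = "channel"))
  ok <- complete.cases(pa[, c("x", "y", "z")]) &
    complete.cases(pb[, c("x", "y", "z")])
  d <- sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2 + (pa$z - pb$z)^2)[ok]
  h <- graphics_free_hist(d, breaks)
  list(distances = tibble(a = pairs$a[ok], b = pairs$b[ok], distance_mm = d),
       histogram = h, n_skipped = sum(!ok))
}

graphics_free_hist <- function(x, breaks) {
  cut_idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  cut_idx <- cut_idx[cut_idx >= 1 & cut_idx < length(breaks)]
  counts <- tabulate(cut_idx, nbins = length(breaks) - 1)
  tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
         count = counts)
}

#' Correlated-channel proportions per lobe and subject
#'
#' For every subject and lobe: the fraction of implanted channels in the
#' correlated class (the non-correlated fraction is the complement). Lobes
#' with zero channels for a subject are omitted for that subject; group
#' means average the subject-level proportions.
#'
#' @param classes Tibble from [classify_and_sort()] results, with columns
#'   `subject`, `channel`, `class`.
#' @param channel_table Channel table with `channel` and `lobe` (see
#'   [assign_lobes()]); `tissue` optional.
#' @param gray_only Restrict to gray-matter contacts (requires a `tissue`
#'   column).
#'
#' @return A list with `per_subject` (subject, lobe, n_channels,
#'   prop_correlated, prop_non_correlated) and `group` (lobe-level means).
#' @export
lobe_proportions <- function(classes, channel_table, gray_only = FALSE) {
  stopifnot(all(c("subject", "channel", "class") %in% names(classes)))
  ct <- as_tibble(channel_table)
  if (gray_only) {
    if (!"tissue" %in% names(ct)) abort("`gray_only` needs a `tissue` column.")
    ct <- filter(ct, .data$tissue == "gray")
  }
  d <- left_join(classes, ct[, c("channel", "lobe")], by = "channel")
  d <- filter(d, !is.na(.data$lobe), .data$lobe != "unassigned")
  per_subject <- summarise(
    group_by(d, .data$subject, .data$lobe),
    n_channels = n(),
    prop_correlated = mean(.data$class == "correlated"),
    .groups = "drop")
  per_subject <- mutate(per_subject,
                        prop_non_correlated = 1 - .data$prop_correlated)
  group <- summarise(group_by(per_subject, .data$lobe),
                     n_subjects = n(),
                     prop_correlated = mean(.data$prop_correlated),
                     prop_non_correlated = mean(.data$prop_non_correlated),
                     .groups = "drop")
  list(per_subject = per_subject, group = group)
}

#' Per-channel word-engagement frequency
#'
#' For each channel and task phase (encoding vs recall), the proportion of
#' words in whose per-word raster the channel participated in coincident
#' bursting (membership in the correlated class for that word). Aggregation
#' across subjects expresses each subject's engaged-channel counts as a
#' proportion of that subject's implanted channels.
#'
#' @param participation Tibble with columns `subject`, `channel`, `phase`
#'   (`"encoding"`/`"recall"`), `item` (word), `engaged` (logical).
#' @param n_channels_per_subject Named vector or tibble (`subject`,
#'   `n_channels`) of implanted-channel counts per subject.
#'
#' @return A list with `per_channel` (subject, channel, phase, n_words,
#'   engagement = engaged words / word pool) and `group` (per subject and
#'   phase: engaged channels as a proportion of implanted channels).
#' @export
engagement_frequency <- function(participation, n_channels_per_subject = NULL) {
  stopifnot(all(c("subject", "channel", "phase", "item", "engaged") %in%
                  names(participation)))
  pool <- summarise(group_by(participation, .data$subject, .data$phase),
                    pool_size = dplyr::n_distinct(.data$item),
                    .groups = "drop")
  if (any(pool$pool_size == 0)) {
    warn("Zero analyzed words for some subject/phase: engagement undefined.")
  }
  per_item <- summarise(
    group_by(participation, .data$subject, .data$channel, .data$phase,
             .data$item),
    engaged = any(.data$engaged), .groups = "drop")
  per_channel <- summarise(
    group_by(per_item, .data$subject, .data$channel, .data$phase),
    n_words = n(),
    engagement = mean(.data$engaged),
    .groups = "drop")
  group <- NULL
  if (!is.null(n_channels_per_subject)) {
    if (is.data.frame(n_channels_per_subject)) {
      nc <- n_channels_per_subject
    } else {
      nc <- tibble(subject = names(n_channels_per_subject),
                   n_channels = unname(n_channels_per_subject))
    }
    engaged_any <- summarise(
      group_by(filter(per_channel, .data$engagement > 0),
               .data$subject, .data$phase),
      n_engaged = n(), .groups = "drop")
    group <- mutate(left_join(engaged_any, nc, by = "subject"),
                    prop_of_implanted = .data$n_engaged / .data$n_channels)
  }
  list(per_channel = per_channel, group = group)
}
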