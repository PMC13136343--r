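#' Normalized co-HFO probability trace
#'
#' Averages subject-level per-bin co-HFO rates across subjects, rescales to
#' per-second units (x 1/bin_width, i.e. x 100 for 10 ms bins), and
#' normalizes so the full vector sums to one. Both the normalized
#' probability vector and the per-second display vector are returned
#' explicitly (normalization absorbs any constant scaling, so their shapes
#' are identical).
#'
#' @param rates Long tibble of subject-level per-bin mean rates with columns
#'   `subject`, `bin` (1-based index), `rate` (mean co-HFO count per bin).
#' @param bin_width Bin width, s (default 0.010).
#' @param window Half-window, s, used only to label bin centers.
#'
#' @return A tibble with `bin`, `bin_center_s`, `probability` (sums to 1),
#'   `per_second_rate`. If all rates are zero, probabilities are zero and
#'   the `"degenerate"` attribute is `TRUE`.
#' @export
cohfo_probability <- function(rates, bin_width = 0.010, window = NULL) {
  stopifnot(all(c("subject", "bin", "rate") %in% names(rates)))
  g <- summarise(group_by(rates, .data$bin),
                 rate = mean(.data$rate), .groups = "drop")
  g <- arrange(g, .data$bin)
  per_second <- g$rate / bin_width
  tot <- sum(per_second)
  degenerate <- tot <= 0
  probability <- if (degenerate) rep(0, length(per_second)) else per_second / tot
  w <- window %||% (max(g$bin) * bin_width / 2)
  out <- tibble(bin = g$bin,
                bin_center_s = g$bin * bin_width - w - bin_width / 2,
                probability = probability,
                per_second_rate = per_second)
  attr(out, "degenerate") <- degenerate
  out
}

#' Co-HFO probability traces by channel class
#'
#' End-to-end peri-event coincidence analysis for one alignment: builds
#' per-trial rasters per subject, classifies channels by their maximum
#' pairwise correlation over the trial-concatenated rasters (recomputed per
#' alignment), counts coincident HFOs within each class, averages within
#' then across subjects, and emits normalized probability traces.
#'
#' @param events HFO event tibble (`subject`, `channel`, `peak_time`, ...).
#' @param align Tibble of align times with columns `subject`, `onset` (s).
#' @param threshold Correlation threshold for the correlated class
#'   (default 0.5).
#' @param bin_width,window Raster geometry (defaults 10 ms, +/-1.5 s).
#' @param t_max Recording length (s) for edge truncation.
#' @param halfwidth_bins Coincidence half-window in bins (default 5).
#'
#' @return A `cohfo_traces` tibble with columns `channel_class`, `bin`,
#'   `bin_center_s`, `probability`, `per_second_rate`, plus a
#'   `classification` attribute (per-subject channel classes).
#' @export
cohfo_traces <- function(events, align, threshold = 0.5, bin_width = 0.010,
                         window = 1.5, t_max = Inf, halfwidth_bins = 5) {
  stopifnot(all(c("subject", "onset") %in% names(align)))
  subjects <- intersect(unique(align$subject), unique(events$subject))
  class_rows <- list()
  rate_rows <- list()
  for (s in subjects) {
    ev_s <- filter(events, .data$subject == s)
    al_s <- filter(align, .data$subject == s)
    channels <- sort(unique(ev_s$channel))
    if (length(channels) < 2 || nrow(al_s) == 0) next
    rasters <- build_raster(ev_s, al_s$onset, bin_width = bin_width,
                            window = window, channels = channels,
                            t_max = t_max)
    if (!length(rasters)) next
    corr <- pairwise_correlation(rasters)
    cls <- classify_and_sort(corr, threshold = threshold)
    cls$subject <- s
    class_rows[[s]] <- cls
    for (k in c("correlated", "non-correlated")) {
      chs <- cls$channel[cls$class == k]
      nb <- ncol(rasters[[1]])
      rate <- if (length(chs) >= 2) {
        counts <- vapply(rasters, function(r)
          count_cohfo(r[chs, , drop = FALSE], halfwidth_bins), integer(nb))
        rowMeans(matrix(counts, ncol = length(rasters)))
      } else {
        rep(0, nb)
      }
      rate_rows[[paste(s, k)]] <- tibble(subject = s, channel_class = k,
                                         bin = seq_len(nb), rate = rate)
    }
  }
  rates <- bind_rows(rate_rows)
  if (nrow(rates) == 0) {
    out <- tibble(channel_class = character(0), bin = integer(0),
                  bin_center_s = numeric(0), probability = numeric(0),
                  per_second_rate = numeric(0))
  } else {
    out <- bind_rows(lapply(split(rates, rates$channel_class), function(d) {
      p <- cohfo_probability(d, bin_width = bin_width, window = window)
      mutate(p, channel_class = d$channel_class[1], .before = 1)
    }))
  }
  structure(out, class = c("cohfo_traces", class(out)),
            classification = bind_rows(class_rows),
            bin_width = bin_width, window = window)
}

#' Paired co-HFO traces for a behavioral contrast
#'
#' Computes probability traces separately per stratum of a contrast with
#' identical binning and windows so per-bin statistics can be run on the
#' aligned traces. Strata with zero align events are flagged and excluded.
#'
#' @param events HFO event tibble.
#' @param task_events Task event tibble (`subject`, `onset`, `duration`,
#'   `trial_type`, `item`, `recalled`).
#' @param contrast One of `"recalled-vs-forgotten"` (word-onset-aligned
#'   encoding trials split by subsequent recall), `"phase-vs-phase"` (the
#'   four task phases aligned to their onsets), or
#'   `"cue-locked-vs-vocalization-locked"` (CUE vs RECALL alignment).
#' @param threshold,bin_width,window,t_max,halfwidth_bins See
#'   [cohfo_traces()].
#'
#' @return A `cohfo_traces` tibble with an additional `condition` column.
#' @export
contrast_traces <- function(events, task_events,
                            contrast = c("recalled-vs-forgotten",
                                         "phase-vs-phase",
                                         "cue-locked-vs-vocalization-locked"),
                            threshold = 0.5, bin_width = 0.010, window = 1.5,
                            t_max = Inf, halfwidth_bins = 5) {
  contrast <- match.arg(contrast)
  strata <- switch(contrast,
    "recalled-vs-forgotten" = {
      w <- filter(task_events, .data$trial_type == "WORD", !is.na(.data$recalled))
      list(recalled = filter(w, .data$recalled),
           forgotten = filter(w, !.data$recalled))
    },
    "phase-vs-phase" = {
      ph <- c(countdown = "COUNTDOWN", encode = "WORD",
              distractor = "DISTRACTOR", recall = "RECALL")
      lapply(ph, function(tt) filter(task_events, .data$trial_type == tt))
    },
    "cue-locked-vs-vocalization-locked" = {
      list(`cue-locked` = filter(task_events, .data$trial_type == "CUE"),
           `vocalization-locked` = filter(task_events, .data$trial_type == "RECALL"))
    }
  )
  keep <- vapply(strata, nrow, integer(1)) > 0
  if (any(!keep)) {
    warn(sprintf("Excluding empty strata: %s",
                 paste(names(strata)[!keep], collapse = ", ")))
  }
  strata <- strata[keep]
  out <- bind_rows(lapply(names(strata), function(nm) {
    tr <- cohfo_traces(events, strata[[nm]][, c("subject", "onset")],
                       threshold = threshold, bin_width = bin_width,
                       window = window, t_max = t_max,
                       halfwidth_bins = halfwidth_bins)
    mutate(as_tibble(tr), condition = nm, .before = 1)
  }))
  structure(out, class = c("cohfo_traces", class(tibble())),
            bin_width = bin_width, window = window)
}

#' Plot co-HFO probability traces
#'
#' @param object A `cohfo_traces` tibble.
#' @param value Which vector to draw: `"probability"` or
#'   `"per_second_rate"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohfo_traces <- function(object, value = c("probability", "per_second_rate"), ...) {
  value <- match.arg(value)
  d <- as_tibble(object)
  aes_col <- if ("condition" %in% names(d)) "condition" else "channel_class"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_center_s,
                                  y = .data[[value]],
                                  colour = .data[[aes_col]],
                                  linetype = .data$channel_class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time from event (s)",
                  y = if (value == "probability") "co-HFO probability"
                      else "co-HFO rate (1/s)") +
    ggplot2::theme_minimal()
}
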