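#' Write a signal record to a float32 container with JSON sidecar
#'
#' Samples are stored channel-major (each channel's samples contiguous) as
#' little-endian float32 in `<prefix>.bin`; sampling rate, channel names,
#' units, subject and sample counts go to `<prefix>.json`.
#'
#' @param record An [lfp_record()].
#' @param prefix Output path prefix (no extension).
#'
#' @return Invisibly, the two file paths.
#' @export
write_signal <- function(record, prefix) {
  stopifnot(inherits(record, "lfp_record"))
  bin_path <- paste0(prefix, ".bin")
  json_path <- paste0(prefix, ".json")
  con <- file(bin_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(record$data), con, size = 4L, endian = "little")
  meta <- list(fs = record$fs, subject = record$subject,
               units = record$units,
               channel_names = channel_labels(record),
               n_channels = n_channels(record),
               n_samples = n_samples(record),
               sample_order = "channel-major")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(bin = bin_path, json = json_path))
}

#' Read a signal record written by [write_signal()]
#'
#' @param prefix Path prefix (no extension).
#'
#' @return An [lfp_record()].
#' @export
read_signal <- function(prefix) {
  bin_path <- paste0(prefix, ".bin")
  json_path <- paste0(prefix, ".json")
  if (!file.exists(bin_path) || !file.exists(json_path)) {
    abort(sprintf("Missing container files for prefix '%s'.", prefix))
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (is.null(meta$fs) || !is.numeric(meta$fs) || meta$fs <= 0) {
    abort("Sidecar has a missing or non-positive `fs`.",
          class = "cohfo_invalid_metadata")
  }
  expected <- meta$n_channels * meta$n_samples
  found_bytes <- file.info(bin_path)$size
  if (found_bytes != 4 * expected) {
    abort(sprintf(
      "Sample-count mismatch: sidecar implies %d bytes (%d samples x %d channels x 4), file has %d bytes.",
      4 * expected, meta$n_samples, meta$n_channels, found_bytes),
      class = "cohfo_format_error")
  }
  con <- file(bin_path, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, "numeric", n = expected, size = 4L, endian = "little")
  data <- matrix(x, nrow = meta$n_samples, ncol = meta$n_channels)
  colnames(data) <- meta$channel_names
  lfp_record(data, fs = meta$fs, subject = meta$subject, units = meta$units)
}

task_trial_types <- c("COUNTDOWN", "WORD", "DISTRACTOR", "RECALL", "CUE")

hfo_event_columns <- c("subject", "channel", "onset", "offset", "peak_time",
                       "dominant_freq", "freq_min", "freq_max", "freq_span",
                       "peak_z", "peak_amplitude")

#' Write an event table as tab-separated text
#'
#' @param events Task-event or HFO-event tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate an event table
#'
#' Tab-separated with a header row. Task tables need `onset`, `duration`,
#' `trial_type`, `item`, `recalled` and restrict `trial_type` to
#' COUNTDOWN/WORD/DISTRACTOR/RECALL/CUE; HFO tables need the standard
#' detector columns. Offending lines are reported by number (header =
#' line 1).
#'
#' @param path Input path.
#' @param type `"task"` or `"hfo"`.
#'
#' @return A typed tibble.
#' @export
read_events <- function(path, type = c("task", "hfo")) {
  type <- match.arg(type)
  d <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  required <- if (type == "task") {
    c("onset", "duration", "trial_type", "item", "recalled")
  } else {
    hfo_event_columns
  }
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "cohfo_format_error")
  }
  num_cols <- if (type == "task") c("onset", "duration") else
    setdiff(required, c("subject", "channel"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(d[[cc]]))
    bad <- which(is.na(v) & !is.na(d[[cc]]) & d[[cc]] != "NA")
    if (length(bad)) {
      abort(sprintf("Non-numeric `%s` at line(s): %s", cc,
                    paste(bad + 1L, collapse = ", ")),
            class = "cohfo_format_error")
    }
    d[[cc]] <- v
  }
  if (type == "task") {
    bad <- which(!(d$trial_type %in% task_trial_types))
    if (length(bad)) {
      abort(sprintf("Unknown trial_type %s at line(s): %s",
                    paste(unique(d$trial_type[bad]), collapse = "/"),
                    paste(bad + 1L, collapse = ", ")),
            class = "cohfo_format_error")
    }
    d$recalled <- as.logical(d$recalled)
  }
  d
}

#' Synthetic channel metadata table
#'
#' A stand-in electrode table for pipeline runs on simulated data: channels
#' are placed on shafts of four contacts with jittered MNI coordinates and
#' regions drawn from the default lobe map. Purely synthetic; labeled as
#' such so it is never mistaken for localized clinical contacts.
#'
#' @param n_channels Number of channels.
#' @param seed RNG seed.
#'
#' @return Tibble with `channel`, `x`, `y`, `z`, `region`, `group`,
#'   `tissue`.
#' @export
synthetic_channel_table <- function(n_channels, seed = 1) {
  set.seed(seed)
  regions <- default_lobe_map()$region
  shaft <- (seq_len(n_channels) - 1) %/% 4 + 1
  base <- matrix(runif(3 * max(shaft), -60, 60), ncol = 3)
  tibble(
    channel = sprintf("ch%02d", seq_len(n_channels)),
    x = base[shaft, 1] + 5 * ((seq_len(n_channels) - 1) %% 4),
    y = base[shaft, 2] + rnorm(n_channels, 0, 2),
    z = base[shaft, 3] + rnorm(n_channels, 0, 2),
    region = sample(regions, n_channels, replace = TRUE),
    group = sprintf("shaft%02d", shaft),
    tissue = sample(c("gray", "white"), n_channels, replace = TRUE,
                    prob = c(0.8, 0.2))
  )
}

pipeline_stages <- c("simulate", "detect", "coincide", "cluster", "stats",
                     "anatomy")

#' Run the full analysis pipeline on simulated data
#'
#' Chains simulate -> detect -> coincide -> cluster -> stats -> anatomy,
#' writing every artifact as tab-separated text plus a JSON manifest with
#' parameter values, seeds, package version, and MD5 hashes of every output
#' — enough to reproduce every byte. Fully deterministic for a fixed config.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of stages to run (unknown names rejected up front).
#'   Later stages re-read earlier artifacts from `out_dir`.
#' @param use_detector Run [detect_hfos()] on the rendered signal (`TRUE`)
#'   or analyze the simulator's ground-truth bursts (`FALSE`, faster).
#' @param threshold Correlation threshold for channel classes.
#' @param n_boot Bootstrap replicates for cluster stability.
#' @param channel_table Channel metadata; default is a synthetic table.
#' @param threads Thread-count hint; accepted for interface compatibility,
#'   results are independent of it (all computation is single-threaded).
#'
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, stages = pipeline_stages,
                         use_detector = FALSE, threshold = 0.5,
                         n_boot = 50, channel_table = NULL, threads = 1L) {
  stopifnot(inherits(config, "sim_config"))
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown)) {
    abort(sprintf("Unknown pipeline stage(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(task = file.path(out_dir, "task_events.tsv"),
                truth = file.path(out_dir, "ground_truth.tsv"),
                events = file.path(out_dir, "events.tsv"),
                traces = file.path(out_dir, "traces.tsv"),
                labels = file.path(out_dir, "cluster_labels.tsv"),
                newick = file.path(out_dir, "cluster_tree.nwk"),
                stability = file.path(out_dir, "stability.tsv"),
                stats = file.path(out_dir, "binwise_stats.tsv"),
                channels = file.path(out_dir, "channels.tsv"),
                anatomy = file.path(out_dir, "lobe_proportions.tsv"),
                manifest = file.path(out_dir, "manifest.json"))

  if ("simulate" %in% stages) {
    sim <- simulate_dataset(config, render_signal = use_detector)
    write_events(sim$task_events, paths$task)
    write_events(sim$ground_truth, paths$truth)
    if (use_detector) {
      for (s in seq_along(sim$signals)) {
        write_signal(sim$signals[[s]],
                     file.path(out_dir, sprintf("signal_S%02d", s)))
      }
    }
  } else {
    sim <- list(task_events = read_events(paths$task, "task"),
                ground_truth = as_tibble(read.delim(paths$truth)))
  }

  if ("detect" %in% stages) {
    events <- if (use_detector) {
      bank <- make_filterbank(fs = config$fs,
                              f_hi = min(800, 0.45 * config$fs),
                              reduce = TRUE)
      bind_rows(lapply(sim$signals %||% list(), function(sg)
        detect_hfos(sg, bank = bank)))
    } else {
      ground_truth_events(sim$ground_truth)
    }
    write_events(events, paths$events)
  } else if (file.exists(paths$events)) {
    events <- read_events(paths$events, "hfo")
  } else {
    events <- ground_truth_events(sim$ground_truth)
  }

  classification <- NULL
  if ("coincide" %in% stages) {
    tr <- contrast_traces(events, sim$task_events, "phase-vs-phase",
                          threshold = threshold, t_max = config$duration)
    write.table(as_tibble(tr), paths$traces, sep = "\t", quote = FALSE,
                row.names = FALSE)
    rec <- filter(sim$task_events, .data$trial_type == "RECALL")
    recall_tr <- cohfo_traces(events, rec[, c("subject", "onset")],
                              threshold = threshold,
                              t_max = config$duration)
    classification <- attr(recall_tr, "classification")
  }

  if ("cluster" %in% stages) {
    s1 <- unique(events$subject)[1]
    ev_s <- filter(events, .data$subject == s1)
    rec <- filter(sim$task_events, .data$trial_type == "RECALL",
                  .data$subject == s1)
    rasters <- build_raster(ev_s, rec$onset,
                            channels = sort(unique(ev_s$channel)),
                            t_max = config$duration)
    if (length(rasters) && nrow(rasters[[1]]) >= 3) {
      cl <- average_linkage_cluster(correlation_distance(rasters))
      write.table(tidy(cl), paths$labels, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      writeLines(cluster_newick(cl), paths$newick)
      st <- bootstrap_stability(concat_rasters(rasters), n_boot = n_boot,
                                seed = config$seed)
      write.table(as_tibble(st), paths$stability, sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  if ("stats" %in% stages) {
    rates <- phase_bin_rates(events, sim$task_events, threshold = threshold,
                             t_max = config$duration)
    if (nrow(rates) && length(unique(rates$subject)) >= 1 &&
        length(unique(rates$condition)) >= 2) {
      res <- add_fdr(per_bin_lmm(rates))
      write.table(res, paths$stats, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }

  if ("anatomy" %in% stages) {
    if (is.null(channel_table)) {
      channel_table <- assign_lobes(
        synthetic_channel_table(config$n_channels, seed = config$seed))
    }
    write.table(channel_table, paths$channels, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(classification) && nrow(classification)) {
      lp <- lobe_proportions(classification, channel_table)
      write.table(lp$per_subject, paths$anatomy, sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  written <- Filter(file.exists, unlist(paths[names(paths) != "manifest"]))
  extra <- list.files(out_dir, pattern = "^signal_.*\\.(bin|json)$",
                      full.names = TRUE)
  written <- sort(unique(c(written, extra)))
  manifest <- list(
    package = "cohfo",
    version = as.character(utils::packageVersion("cohfo")),
    seed = config$seed,
    threads_hint = as.integer(threads),
    stages = stages,
    parameters = list(
      n_subjects = config$n_subjects, n_channels = config$n_channels,
      fs = config$fs, duration = config$duration,
      noise_exponent = config$noise_exponent, noise_rms = config$noise_rms,
      n_lists = config$n_lists, task = config$task,
      threshold = threshold, n_boot = n_boot,
      use_detector = use_detector
    ),
    outputs = lapply(stats::setNames(as.list(written), basename(written)),
                     function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Subject-level per-bin co-HFO rates by task phase
#'
#' The long table feeding [per_bin_lmm()]: for each subject and task phase,
#' the correlated-class per-bin mean co-HFO count across that phase's
#' trials.
#'
#' @inheritParams contrast_traces
#' @return Tibble with `subject`, `condition`, `bin`, `value`.
#' @export
phase_bin_rates <- function(events, task_events, threshold = 0.5,
                            bin_width = 0.010, window = 1.5, t_max = Inf,
                            halfwidth_bins = 5) {
  ph <- c(countdown = "COUNTDOWN", encode = "WORD",
          distractor = "DISTRACTOR", recall = "RECALL")
  rows <- list()
  for (nm in names(ph)) {
    al <- filter(task_events, .data$trial_type == ph[[nm]])
    if (!nrow(al)) next
    for (s in intersect(unique(al$subject), unique(events$subject))) {
      ev_s <- filter(events, .data$subject == s)
      channels <- sort(unique(ev_s$channel))
      if (length(channels) < 2) next
      al_s <- filter(al, .data$subject == s)
      rasters <- build_raster(ev_s, al_s$onset, bin_width = bin_width,
                              window = window, channels = channels,
                              t_max = t_max)
      if (!length(rasters)) next
      cls <- classify_and_sort(pairwise_correlation(rasters), threshold)
      chs <- cls$channel[cls$class == "correlated"]
      nb <- ncol(rasters[[1]])
      value <- if (length(chs) >= 2) {
        counts <- vapply(rasters, function(r)
          count_cohfo(r[chs, , drop = FALSE], halfwidth_bins), integer(nb))
        rowMeans(matrix(counts, ncol = length(rasters)))
      } else rep(0, nb)
      rows[[paste(nm, s)]] <- tibble(subject = s, condition = nm,
                                     bin = seq_len(nb), value = value)
    }
  }
  bind_rows(rows)
}
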