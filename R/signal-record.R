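#' Multichannel LFP signal record
#'
#' A light container for a multichannel local field potential recording:
#' a samples-by-channels numeric matrix plus sampling rate and channel
#' metadata. All downstream detection functions consume this class.
#'
#' @param data Numeric matrix, samples in rows, channels in columns. Column
#'   names are used as channel labels (defaults `ch01`, `ch02`, ...).
#' @param fs Sampling rate in Hz.
#' @param subject Subject identifier.
#' @param channels Optional tibble of channel metadata (one row per channel,
#'   must contain a `channel` column matching the column names of `data`).
#' @param units Signal units (default `"uV"`).
#'
#' @return An object of class `lfp_record`.
#' @export
lfp_record <- function(data, fs, subject = "S01", channels = NULL, units = "uV") {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric matrix (samples x channels).")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  if (is.null(colnames(data))) {
    colnames(data) <- sprintf("ch%02d", seq_len(ncol(data)))
  }
  if (is.null(channels)) {
    channels <- tibble(channel = colnames(data))
  } else {
    channels <- as_tibble(channels)
    if (!"channel" %in% names(channels)) {
      abort("`channels` metadata must contain a `channel` column.")
    }
  }
  structure(
    list(data = data, fs = fs, subject = subject,
         channels = channels, units = units),
    class = "lfp_record"
  )
}

#' @export
print.lfp_record <- function(x, ...) {
  cat(sprintf(
    "<lfp_record> subject %s: %d channel(s) x %d samples @ %g Hz (%.1f s, %s)\n",
    x$subject, ncol(x$data), nrow(x$data), x$fs,
    nrow(x$data) / x$fs, x$units
  ))
  invisible(x)
}

#' @export
dim.lfp_record <- function(x) dim(x$data)

n_samples <- function(x) nrow(x$data)
n_channels <- function(x) ncol(x$data)
duration_s <- function(x) nrow(x$data) / x$fs
channel_labels <- function(x) colnames(x$data)
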