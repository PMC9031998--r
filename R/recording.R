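#' Construct a multichannel recording
#'
#' A recording is the raw input of the scoring pipeline: a channels-by-samples
#' numeric matrix (amplitudes in microvolts), a sampling rate in Hz, and one
#' unique label per channel. Values must be finite; no preprocessing (filtering,
#' detrending, re-referencing) is ever applied by this package -- that is the
#' caller's responsibility.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique, non-empty labels, one per
#'   channel. Defaults to \code{"ch01"}, \code{"ch02"}, ...
#' @return An object of class \code{eeg_recording} with elements \code{data},
#'   \code{fs} and \code{channel_labels}.
#' @examples
#' rec <- recording(matrix(rnorm(3 * 800), nrow = 3), fs = 160)
#' rec
#' @export
recording <- function(data, fs, channel_labels = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("`data` must have at least one channel and one sample")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values; reject or repair them before scoring")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (is.null(channel_labels))
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("`channel_labels` must have one entry per channel (",
         nrow(data), " channels, ", length(channel_labels), " labels)")
  if (anyDuplicated(channel_labels) || any(!nzchar(channel_labels)))
    stop("`channel_labels` must be unique and non-empty")
  structure(
    list(data = unname(data), fs = as.numeric(fs), channel_labels = channel_labels),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Segment a recording into non-overlapping epochs
#'
#' Cuts the recording into contiguous, non-overlapping epochs of
#' \code{floor(epoch_length_s * fs)} samples, starting at the first sample.
#' Remainder samples at the tail are discarded; epoch data are verbatim slices
#' of the input (no filtering or detrending).
#'
#' @param rec an \code{\link{recording}}.
#' @param epoch_length_s epoch length in seconds.
#' @return An object of class \code{epoch_tensor}: a list with \code{data}
#'   (array, n_epochs x channels x samples_per_epoch), \code{epoch_length_s},
#'   \code{fs}, \code{channel_labels} and \code{source_offsets} (0-based start
#'   sample of each epoch in the parent recording).
#' @examples
#' rec <- recording(matrix(rnorm(2 * 9600), nrow = 2), fs = 160)
#' ep <- segment_recording(rec, 5)  # twelve 5-s epochs of 800 samples
#' dim(ep$data)
#' @export
segment_recording <- function(rec, epoch_length_s) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(epoch_length_s) || length(epoch_length_s) != 1L ||
      !is.finite(epoch_length_s) || epoch_length_s <= 0)
    stop("`epoch_length_s` must be a single positive number (seconds)")
  spe <- floor(epoch_length_s * rec$fs)
  if (spe < 1L)
    stop("epoch_length_s * fs must be at least 1 sample")
  total <- ncol(rec$data)
  if (total < spe)
    stop(sprintf("recording too short: one epoch needs %d samples but only %d are available",
                 spe, total))
  n_epochs <- total %/% spe
  n_ch <- nrow(rec$data)
  used <- rec$data[, seq_len(n_epochs * spe), drop = FALSE]
  # (channels, samples) -> (epochs, channels, samples_per_epoch)
  arr <- array(NA_real_, dim = c(n_epochs, n_ch, spe))
  for (e in seq_len(n_epochs)) {
    arr[e, , ] <- used[, ((e - 1L) * spe + 1L):(e * spe), drop = FALSE]
  }
  structure(
    list(data = arr,
         epoch_length_s = epoch_length_s,
         fs = rec$fs,
         channel_labels = rec$channel_labels,
         source_offsets = (seq_len(n_epochs) - 1L) * spe),
    class = "epoch_tensor"
  )
}

#' @export
print.epoch_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_tensor> %d epoch(s) x %d channel(s) x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}
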