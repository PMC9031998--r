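#' Welch estimator configuration
#'
#' Parameters of the averaged-modified-periodogram (Welch) spectral estimator.
#' Defaults follow common resting-state EEG practice: 1-second Hann segments
#' (1 Hz resolution) with 50 % overlap, density scaling, segment-mean removal.
#' If \code{window_s} is \code{NULL} the segment length is
#' \code{min(fs * 1 s, epoch samples)}, so short epochs still work; an
#' explicitly requested window longer than the epoch is an error.
#'
#' @param window_s segment length in seconds, or \code{NULL} for the adaptive
#'   default described above.
#' @param overlap_fraction fractional overlap between consecutive segments,
#'   in [0, 1).
#' @param window_shape one of \code{"hann"}, \code{"hamming"}, \code{"rect"}.
#' @return A \code{welch_config} list.
#' @export
welch_config <- function(window_s = NULL, overlap_fraction = 0.5,
                         window_shape = c("hann", "hamming", "rect")) {
  window_shape <- match.arg(window_shape)
  if (!is.null(window_s)) {
    if (!is.numeric(window_s) || length(window_s) != 1L || window_s <= 0)
      stop("`window_s` must be NULL or a single positive number (seconds)")
  }
  if (!is.numeric(overlap_fraction) || length(overlap_fraction) != 1L ||
      overlap_fraction < 0 || overlap_fraction >= 1)
    stop("`overlap_fraction` must lie in [0, 1)")
  structure(list(window_s = window_s, overlap_fraction = overlap_fraction,
                 window_shape = window_shape),
            class = "welch_config")
}

# Periodic window (DFT-even), the convention of spectral analysis.
welch_window <- function(n, shape) {
  k <- seq_len(n) - 1L
  switch(shape,
         hann    = 0.5 - 0.5 * cos(2 * pi * k / n),
         hamming = 0.54 - 0.46 * cos(2 * pi * k / n),
         rect    = rep(1, n))
}

#' Welch power spectral density per epoch and channel
#'
#' Estimates one PSD (units microvolt^2/Hz, one-sided density scaling) for every
#' (epoch, channel) pair by averaging windowed, overlapping, mean-removed
#' segment periodograms. The frequency grid is restricted to
#' \code{freq_range} (bin centers, inclusive edges) and is identical across
#' epochs and channels.
#'
#' @param epochs an \code{\link{segment_recording}} epoch tensor.
#' @param freq_range numeric length-2, \code{c(f_min, f_max)} in Hz with
#'   \code{f_min < f_max <= fs/2}.
#' @param welch_cfg a \code{\link{welch_config}}.
#' @return An object of class \code{psd_set}: \code{psd} (array, n_epochs x
#'   channels x n_freq_bins), \code{freqs}, \code{freq_range}, \code{fs},
#'   \code{channel_labels}, \code{welch_cfg}.
#' @examples
#' rec <- recording(matrix(sin(2 * pi * 10 * (0:9599) / 160), nrow = 1), fs = 160)
#' p <- welch_psd(segment_recording(rec, 5), c(1, 40))
#' p$freqs[which.max(p$psd[1, 1, ])]  # 10 Hz
#' @export
welch_psd <- function(epochs, freq_range = c(1, 40), welch_cfg = welch_config()) {
  stopifnot(inherits(epochs, "epoch_tensor"))
  if (!is.numeric(freq_range) || length(freq_range) != 2L ||
      !all(is.finite(freq_range)) || freq_range[1] >= freq_range[2])
    stop("`freq_range` must be c(f_min, f_max) with f_min < f_max")
  fs <- epochs$fs
  if (freq_range[2] > fs / 2)
    stop(sprintf("f_max = %g Hz exceeds the Nyquist frequency %g Hz", freq_range[2], fs / 2))
  d <- dim(epochs$data)
  n_epochs <- d[1]; n_ch <- d[2]; spe <- d[3]

  if (is.null(welch_cfg$window_s)) {
    nper <- min(round(fs), spe)
  } else {
    nper <- round(welch_cfg$window_s * fs)
    if (nper > spe)
      stop(sprintf("Welch segment (%d samples) longer than epoch (%d samples)", nper, spe))
  }
  if (nper < 2L) stop("Welch segment must contain at least 2 samples")
  step <- max(1L, round(nper * (1 - welch_cfg$overlap_fraction)))
  n_seg <- (spe - nper) %/% step + 1L

  w <- welch_window(nper, welch_cfg$window_shape)
  scale <- 1 / (fs * sum(w^2))

  # All (epoch, channel, segment) slices as columns of one matrix, then one FFT.
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = spe)  # spe x (n_ch*n_epochs)
  idx <- outer(seq_len(nper), (seq_len(n_seg) - 1L) * step, `+`)
  segm <- flat[as.vector(idx), , drop = FALSE]
  dim(segm) <- c(nper, n_seg * n_ch * n_epochs)
  segm <- sweep(segm, 2L, colMeans(segm))          # constant detrend per segment
  segm <- segm * w
  spec <- Mod(stats::mvfft(segm))^2 * scale

  n_bins_all <- nper %/% 2L + 1L
  spec <- spec[seq_len(n_bins_all), , drop = FALSE]
  # one-sided: double everything except DC and (for even nper) Nyquist
  dbl <- rep(2, n_bins_all); dbl[1L] <- 1
  if (nper %% 2L == 0L) dbl[n_bins_all] <- 1
  spec <- spec * dbl

  # average periodograms over segments
  dim(spec) <- c(n_bins_all, n_seg, n_ch * n_epochs)
  avg <- colMeans(aperm(spec, c(2, 1, 3)))         # (n_bins_all) x (n_ch*n_epochs)
  dim(avg) <- c(n_bins_all, n_ch, n_epochs)

  freqs_all <- (seq_len(n_bins_all) - 1L) * fs / nper
  keep <- which(freqs_all >= freq_range[1] & freqs_all <= freq_range[2])
  if (length(keep) < 1L)
    stop("no Welch frequency bins fall inside `freq_range`")

  psd <- aperm(avg[keep, , , drop = FALSE], c(3, 2, 1))  # epochs x channels x bins
  structure(
    list(psd = psd, freqs = freqs_all[keep], freq_range = as.numeric(freq_range),
         fs = fs, channel_labels = epochs$channel_labels, welch_cfg = welch_cfg),
    class = "psd_set"
  )
}

#' @export
print.psd_set <- function(x, ...) {
  d <- dim(x$psd)
  cat(sprintf("<psd_set> %d epoch(s) x %d channel(s) x %d bins, %g-%g Hz\n",
              d[1], d[2], d[3], min(x$freqs), max(x$freqs)))
  invisible(x)
}
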