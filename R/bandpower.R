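# Relative band power features (the classic eyes-open / eyes-closed
# discriminator when the band is alpha, 8-13 Hz).

#' Define a frequency band
#'
#' @param name band name (e.g. \code{"alpha"}).
#' @param f_low,f_high band edges in Hz, \code{0 <= f_low < f_high}. Both edges
#'   are inclusive; a PSD bin belongs to the band if its center frequency lies
#'   in \code{[f_low, f_high]}.
#' @return A \code{band_definition} list.
#' @export
band_definition <- function(name, f_low, f_high) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string")
  if (!is.numeric(f_low) || !is.numeric(f_high) ||
      length(f_low) != 1L || length(f_high) != 1L ||
      f_low < 0 || f_low >= f_high)
    stop("band edges must satisfy 0 <= f_low < f_high")
  structure(list(name = name, f_low = as.numeric(f_low), f_high = as.numeric(f_high)),
            class = "band_definition")
}

#' The alpha band, 8-13 Hz
#' @return A \code{\link{band_definition}} for 8-13 Hz.
#' @export
alpha_band <- function() band_definition("alpha", 8, 13)

#' Relative band power per epoch and channel
#'
#' For each (epoch, channel), the sum of PSD bins whose center frequency falls
#' inside the band (inclusive edges), divided by the sum over all bins retained
#' in the PSD set's frequency range. Rectangle (bin-sum) integration is used so
#' results are bit-reproducible; the common bin width cancels in the ratio.
#' The global value is the unweighted mean across channels.
#'
#' @param psds a \code{\link{welch_psd}} result.
#' @param band a \code{\link{band_definition}}.
#' @return An object of class \code{band_power}: \code{per_epoch_per_channel}
#'   (n_epochs x channels, values in [0, 1]) and \code{per_epoch_global}
#'   (length n_epochs).
#' @examples
#' rec <- recording(matrix(rnorm(2 * 9600), nrow = 2), fs = 160)
#' p <- welch_psd(segment_recording(rec, 5), c(1, 40))
#' relative_band_power(p, alpha_band())$per_epoch_global
#' @export
relative_band_power <- function(psds, band) {
  stopifnot(inherits(psds, "psd_set"), inherits(band, "band_definition"))
  in_band <- psds$freqs >= band$f_low & psds$freqs <= band$f_high
  if (!any(in_band))
    stop(sprintf("band %s [%g, %g] Hz has no bins inside the PSD range [%g, %g] Hz",
                 band$name, band$f_low, band$f_high,
                 psds$freq_range[1], psds$freq_range[2]))
  d <- dim(psds$psd)
  total <- apply(psds$psd, c(1, 2), sum)
  if (any(total <= 0))
    stop("zero total power in at least one (epoch, channel); relative power undefined")
  num <- apply(psds$psd[, , in_band, drop = FALSE], c(1, 2), sum)
  rel <- num / total
  structure(
    list(per_epoch_per_channel = rel,
         per_epoch_global = rowMeans(rel),
         band = band),
    class = "band_power"
  )
}
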