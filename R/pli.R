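# Phase lag index connectivity. The PLI between two channels is the absolute
# time-average of the sign of their instantaneous phase difference: 0 when
# phase differences are symmetric around zero (including identical, zero-lag
# signals -- hence insensitivity to volume conduction), 1 when one channel
# consistently leads the other.

# Zero-phase band-pass + analytic signal for one matrix of column signals,
# done in a single FFT pass. H(f) is 1 inside the band and rolls off with a
# raised-cosine taper of width `transition_hz` on each side; the analytic
# multiplier doubles positive frequencies. Exactly zero-phase by construction.
analytic_bandpass <- function(x, fs, f_low, f_high, transition_hz = 1) {
  n <- nrow(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- ifelse(f > fs / 2, fs - f, f)          # |frequency| of each DFT bin
  H <- numeric(n)
  H[f >= f_low & f <= f_high] <- 1
  lo <- f >= f_low - transition_hz & f < f_low
  H[lo] <- 0.5 * (1 + cos(pi * (f_low - f[lo]) / transition_hz))
  hi <- f > f_high & f <= f_high + transition_hz
  H[hi] <- 0.5 * (1 + cos(pi * (f[hi] - f_high) / transition_hz))
  h <- numeric(n)                             # analytic-signal multiplier
  half <- if (n %% 2L == 0L) n / 2 + 1 else (n + 1) / 2
  h[1L] <- 1
  h[2:(half - (n %% 2L == 0L))] <- 2
  if (n %% 2L == 0L) h[n / 2 + 1] <- 1
  h[2:n][f[2:n] == 0] <- 1                    # guard (never triggered for n > 1)
  X <- stats::mvfft(x)
  stats::mvfft(X * (H * h), inverse = TRUE) / n
}

#' Instantaneous phase of band-limited epochs
#'
#' Per epoch and channel: zero-phase band-pass to \code{band} (FFT-domain
#' filter with a raised-cosine transition of \code{transition_hz} on each
#' side), then the phase of the analytic signal. A fraction of samples at each
#' epoch edge (default 5 %) is flagged for exclusion from downstream averaging
#' to suppress filter and analytic-signal transients.
#'
#' @param epochs an \code{\link{segment_recording}} epoch tensor.
#' @param band a \code{\link{band_definition}} within Nyquist.
#' @param transition_hz width of the filter's transition band, Hz.
#' @param edge_fraction fraction of samples excluded at each epoch edge.
#' @return An object of class \code{phase_tensor}: \code{phase} (array,
#'   n_epochs x channels x samples, radians in (-pi, pi]) and \code{interior}
#'   (logical sample mask).
#' @export
instantaneous_phase <- function(epochs, band = alpha_band(),
                                transition_hz = 1, edge_fraction = 0.05) {
  stopifnot(inherits(epochs, "epoch_tensor"), inherits(band, "band_definition"))
  fs <- epochs$fs
  if (band$f_high + transition_hz > fs / 2)
    stop(sprintf("band [%g, %g] Hz (+%g Hz transition) exceeds Nyquist %g Hz",
                 band$f_low, band$f_high, transition_hz, fs / 2))
  d <- dim(epochs$data)
  n_epochs <- d[1]; n_ch <- d[2]; spe <- d[3]
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = spe)
  a <- analytic_bandpass(flat, fs, band$f_low, band$f_high, transition_hz)
  ph <- Arg(a)
  dim(ph) <- c(spe, n_ch, n_epochs)
  n_edge <- floor(edge_fraction * spe)
  interior <- rep(TRUE, spe)
  if (n_edge > 0L) {
    interior[seq_len(n_edge)] <- FALSE
    interior[(spe - n_edge + 1L):spe] <- FALSE
  }
  if (sum(interior) < 2L) stop("fewer than 2 interior samples after edge exclusion")
  structure(
    list(phase = aperm(ph, c(3, 2, 1)), interior = interior,
         band = band, fs = fs, channel_labels = epochs$channel_labels),
    class = "phase_tensor"
  )
}

#' Phase lag index per epoch
#'
#' For every channel pair (a, b) and epoch, PLI = |mean over interior samples
#' of sign(phase_a - phase_b)|, with the phase difference wrapped to
#' (-pi, pi] -- implemented as sign(sin(phase_a - phase_b)), the standard
#' convention -- and sign(0) contributing 0 (neither lead nor lag). The global
#' per-epoch value is the mean over distinct pairs a < b.
#'
#' @param phases a \code{\link{instantaneous_phase}} result.
#' @return An object of class \code{pli_result}: \code{per_epoch_matrix}
#'   (array, n_epochs x channels x channels, symmetric, zero diagonal, values
#'   in [0, 1]) and \code{per_epoch_global} (length n_epochs).
#' @export
phase_lag_index <- function(phases) {
  stopifnot(inherits(phases, "phase_tensor"))
  d <- dim(phases$phase)
  n_epochs <- d[1]; n_ch <- d[2]
  if (n_ch < 2L) stop("PLI needs at least 2 channels (no pairs for a single channel)")
  keep <- which(phases$interior)
  mat <- array(0, dim = c(n_epochs, n_ch, n_ch))
  for (e in seq_len(n_epochs)) {
    ph <- matrix(phases$phase[e, , keep], nrow = n_ch)  # channels x interior
    for (a in seq_len(n_ch - 1L)) {
      dphi <- sweep(ph[(a + 1L):n_ch, , drop = FALSE], 2L, ph[a, ])
      v <- abs(rowMeans(sign(sin(dphi))))
      mat[e, a, (a + 1L):n_ch] <- v
      mat[e, (a + 1L):n_ch, a] <- v
    }
  }
  upper <- upper.tri(matrix(0, n_ch, n_ch))
  glob <- apply(mat, 1L, function(m) mean(m[upper]))
  structure(list(per_epoch_matrix = mat, per_epoch_global = glob,
                 band = phases$band),
            class = "pli_result")
}

#' Global PLI per epoch of a recording
#'
#' Convenience wrapper: segment, band-limit (default alpha, 8-13 Hz), extract
#' instantaneous phases, and compute the per-epoch global phase lag index.
#'
#' @inheritParams score_epochs
#' @param band a \code{\link{band_definition}} (default alpha 8-13 Hz).
#' @param ... passed to \code{\link{instantaneous_phase}}.
#' @return numeric vector, one global PLI per epoch.
#' @export
pli_epochs <- function(rec, epoch_length_s = 5, band = alpha_band(), ...) {
  ep <- segment_recording(rec, epoch_length_s)
  phase_lag_index(instantaneous_phase(ep, band, ...))$per_epoch_global
}
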