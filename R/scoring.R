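# Epoch quality scoring: per-channel Spearman similarity of epoch spectra,
# row means -> per-channel score vectors, channel mean -> per-epoch scores.

# Epochs whose PSD vector is constant have zero rank variance; Spearman
# correlation against them is undefined.
find_degenerate_epochs <- function(x) {
  which(apply(x, 1L, function(v) all(v == v[1L])))
}

#' Spearman similarity matrix between epoch spectra of one channel
#'
#' Entry (i, j) is the Spearman rank correlation (mid-ranks for ties) between
#' the PSD vectors of epochs i and j over the retained frequency bins. The
#' result is symmetric with a unit diagonal.
#'
#' @param psds a \code{\link{welch_psd}} result.
#' @param channel channel index (1-based).
#' @return n_epochs x n_epochs symmetric matrix of correlations in [-1, 1].
#' @export
spearman_similarity <- function(psds, channel) {
  stopifnot(inherits(psds, "psd_set"))
  d <- dim(psds$psd)
  if (d[3] < 2L) stop("need at least 2 frequency bins for rank correlation")
  if (channel < 1L || channel > d[2]) stop("channel index out of range")
  x <- psds$psd[, channel, , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = d[1])
  deg <- find_degenerate_epochs(x)
  if (length(deg))
    stop(sprintf("degenerate (constant) spectrum: epoch %s, channel %d (%s); %s",
                 paste(deg, collapse = ","), channel, psds$channel_labels[channel],
                 "similarity is undefined for a flat spectrum"))
  s <- stats::cor(t(x), method = "spearman")
  s[s > 1] <- 1; s[s < -1] <- -1
  diag(s) <- 1
  (s + t(s)) / 2
}

#' Per-channel score vector from a similarity matrix
#'
#' The score of epoch e on a channel is the mean of row e of that channel's
#' epoch-by-epoch similarity matrix, diagonal included. Because the diagonal is
#' identically 1, including it is an affine (hence rank-preserving) transform
#' of the off-diagonal mean, so the final epoch ranking does not depend on this
#' convention.
#'
#' @param similarity square symmetric matrix with unit diagonal.
#' @return numeric vector of per-epoch scores in [-1, 1].
#' @export
channel_score_vector <- function(similarity) {
  if (!is.matrix(similarity) || nrow(similarity) != ncol(similarity))
    stop("`similarity` must be a square matrix")
  if (max(abs(similarity - t(similarity))) > 1e-8 ||
      max(abs(diag(similarity) - 1)) > 1e-8)
    stop("`similarity` must be symmetric with a unit diagonal")
  rowMeans(similarity)
}

#' Aggregate per-channel score vectors into final epoch scores
#'
#' @param score_vectors channels x n_epochs matrix.
#' @return numeric vector of length n_epochs (unweighted mean across channels).
#' @export
aggregate_scores <- function(score_vectors) {
  if (!is.matrix(score_vectors) || nrow(score_vectors) < 1L)
    stop("`score_vectors` must be a matrix with at least one channel row")
  colMeans(score_vectors)
}

#' Rank epochs by score, best first
#'
#' Stable descending sort; ties are broken by ascending epoch index so results
#' are reproducible. Callers take the first k entries as the suggested
#' selection.
#'
#' @param scores numeric vector of finite per-epoch scores.
#' @return integer permutation of \code{seq_along(scores)} (1-based).
#' @export
rank_epochs <- function(scores) {
  if (!is.numeric(scores) || length(scores) < 1L)
    stop("`scores` must be a non-empty numeric vector")
  if (!all(is.finite(scores)))
    stop("non-finite score at epoch ", paste(which(!is.finite(scores)), collapse = ","))
  order(-scores, seq_along(scores))
}

# Re-raise any stage error with a tag naming the failing pipeline stage.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Score all epochs of a recording
#'
#' Runs the full scoring pipeline: segment the recording into non-overlapping
#' epochs, estimate each (epoch, channel) PSD by the Welch method over
#' \code{freq_range}, correlate epoch spectra within each channel (Spearman),
#' average similarity-matrix rows into per-channel score vectors, average
#' those across channels into one score per epoch, and rank epochs by
#' descending score. All intermediates are retained in the result.
#'
#' Epochs with a constant (flat) spectrum on some channel have no defined rank
#' correlation. By default this is an error; with
#' \code{on_degenerate = "rank_last"} such epochs instead receive score
#' \code{-Inf} and are placed at the end of the ranking.
#'
#' @param rec an \code{\link{recording}}.
#' @param epoch_length_s epoch length in seconds (default 5).
#' @param freq_range frequency range in Hz for the PSD comparison
#'   (default \code{c(1, 40)}).
#' @param welch_cfg a \code{\link{welch_config}}.
#' @param on_degenerate \code{"error"} (default) or \code{"rank_last"}.
#' @return An object of class \code{epoch_scores}: \code{similarity} (array,
#'   channels x n_epochs x n_epochs), \code{score_vectors} (channels x
#'   n_epochs), \code{scores} (n_epochs), \code{ranking} (1-based permutation,
#'   best epoch first), plus the configuration used.
#' @examples
#' rec <- recording(matrix(rnorm(4 * 9600), nrow = 4), fs = 160)
#' sc <- score_epochs(rec, epoch_length_s = 5)
#' sc$ranking[1:4]  # suggested four epochs
#' @export
score_epochs <- function(rec, epoch_length_s = 5, freq_range = c(1, 40),
                         welch_cfg = welch_config(),
                         on_degenerate = c("error", "rank_last")) {
  on_degenerate <- match.arg(on_degenerate)
  epochs <- with_stage("segment", segment_recording(rec, epoch_length_s))
  psds <- with_stage("welch_psd", welch_psd(epochs, freq_range, welch_cfg))
  d <- dim(psds$psd)
  n_epochs <- d[1]; n_ch <- d[2]

  degenerate <- integer(0)
  if (on_degenerate == "rank_last") {
    for (c in seq_len(n_ch)) {
      x <- matrix(psds$psd[, c, ], nrow = n_epochs)
      degenerate <- union(degenerate, find_degenerate_epochs(x))
    }
    degenerate <- sort(degenerate)
  }
  ok <- setdiff(seq_len(n_epochs), degenerate)
  if (length(ok) < 2L && length(degenerate) > 0L)
    stop("[spearman_similarity] fewer than 2 non-degenerate epochs remain")

  similarity <- array(NA_real_, dim = c(n_ch, n_epochs, n_epochs))
  score_vectors <- matrix(NA_real_, nrow = n_ch, ncol = n_epochs)
  sub <- structure(list(psd = psds$psd[ok, , , drop = FALSE], freqs = psds$freqs,
                        freq_range = psds$freq_range, fs = psds$fs,
                        channel_labels = psds$channel_labels,
                        welch_cfg = psds$welch_cfg),
                   class = "psd_set")
  for (c in seq_len(n_ch)) {
    s <- with_stage("spearman_similarity", spearman_similarity(sub, c))
    similarity[c, ok, ok] <- s
    score_vectors[c, ok] <- with_stage("channel_score_vector", channel_score_vector(s))
  }
  scores <- rep(-Inf, n_epochs)
  scores[ok] <- with_stage("aggregate_scores",
                           aggregate_scores(score_vectors[, ok, drop = FALSE]))
  ranking <- c(ok[with_stage("rank_epochs", rank_epochs(scores[ok]))], degenerate)

  structure(
    list(similarity = similarity, score_vectors = score_vectors,
         scores = scores, ranking = as.integer(ranking),
         degenerate_epochs = as.integer(degenerate),
         epoch_length_s = epoch_length_s, freq_range = as.numeric(freq_range),
         welch_cfg = welch_cfg, fs = rec$fs,
         channel_labels = rec$channel_labels,
         n_epochs = n_epochs),
    class = "epoch_scores"
  )
}

#' @export
print.epoch_scores <- function(x, ...) {
  cat(sprintf("<epoch_scores> %d epochs x %d channels, %g s epochs, %g-%g Hz\n",
              x$n_epochs, nrow(x$score_vectors), x$epoch_length_s,
              x$freq_range[1], x$freq_range[2]))
  cat("scores (by epoch):", format(round(x$scores, 4)), "\n")
  cat("ranking (best first, 1-based):", x$ranking, "\n")
  invisible(x)
}
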