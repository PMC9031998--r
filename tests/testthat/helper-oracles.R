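# Independent oracles and small fixture builders. These deliberately use
# explicit loops and textbook formulas, never the package's own code paths.

# Spearman correlation via mid-ranks + the Pearson formula on ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Full scoring stack on a PSD array (epochs x channels x bins), loop-based.
oracle_scores_from_psd <- function(psd) {
  n_e <- dim(psd)[1]; n_c <- dim(psd)[2]
  sv <- matrix(0, n_c, n_e)
  for (c in seq_len(n_c)) {
    s <- diag(n_e)
    for (i in seq_len(n_e)) for (j in seq_len(n_e)) {
      if (i != j) s[i, j] <- oracle_spearman(psd[i, c, ], psd[j, c, ])
    }
    for (e in seq_len(n_e)) sv[c, e] <- mean(s[e, ])
  }
  scores <- numeric(n_e)
  for (e in seq_len(n_e)) scores[e] <- mean(sv[, e])
  scores
}

# Wrap a raw psd array in a psd_set so package functions accept it.
make_psd_set <- function(psd, freqs, freq_range = range(freqs), fs = 160) {
  structure(list(psd = psd, freqs = freqs, freq_range = as.numeric(freq_range),
                 fs = fs, channel_labels = sprintf("ch%02d", seq_len(dim(psd)[2])),
                 welch_cfg = welch_config()),
            class = "psd_set")
}

# Recording made of one epoch-long segment tiled n times (all epochs equal).
tiled_recording <- function(n_tiles = 12, n_ch = 3, fs = 160, epoch_s = 5, seed = 7) {
  set.seed(seed)
  seg <- matrix(rnorm(n_ch * fs * epoch_s), nrow = n_ch)
  recording(do.call(cbind, rep(list(seg), n_tiles)), fs)
}

# Reorder the epochs of a recording (permutation of verbatim slices).
permute_epochs <- function(rec, epoch_s, perm) {
  spe <- floor(epoch_s * rec$fs)
  cols <- unlist(lapply(perm, function(e) ((e - 1L) * spe + 1L):(e * spe)))
  recording(rec$data[, cols, drop = FALSE], rec$fs, rec$channel_labels)
}

# Phase tensor built directly from a phase array (epochs x channels x samples).
make_phase_tensor <- function(phase, interior = rep(TRUE, dim(phase)[3])) {
  structure(list(phase = phase, interior = interior, band = alpha_band(),
                 fs = 160, channel_labels = sprintf("ch%02d", seq_len(dim(phase)[2]))),
            class = "phase_tensor")
}
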