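# Core scoring pipeline: segmentation, Welch PSD, Spearman similarity,
# score vectors, aggregation, ranking, and the composed score_epochs().

test_that("segmentation produces non-overlapping contiguous epochs and drops the tail", {
  rec <- recording(matrix(rnorm(2 * 9600), nrow = 2), fs = 160)

  ep5 <- segment_recording(rec, 5)
  expect_equal(dim(ep5$data), c(12, 2, 800))
  expect_equal(ep5$source_offsets, (0:11) * 800)
  expect_equal(ep5$data[3, 2, ], rec$data[2, 1601:2400])  # verbatim slice

  ep8 <- segment_recording(rec, 8)                        # 4 s remainder dropped
  expect_equal(dim(ep8$data)[1], 7)

  one <- recording(matrix(rnorm(800), nrow = 1), fs = 160)
  ep1 <- segment_recording(one, 5)
  expect_equal(dim(ep1$data)[1], 1)
  expect_equal(ep1$source_offsets, 0)

  short <- recording(matrix(rnorm(300), nrow = 1), fs = 160)
  expect_error(segment_recording(short, 5), "800 samples but only 300")
})

test_that("recordings reject non-finite data and bad metadata", {
  m <- matrix(rnorm(100), nrow = 2)
  m[1, 3] <- NA
  expect_error(recording(m, 160), "non-finite")
  expect_error(recording(matrix(1:4, 2), 0), "positive")
  expect_error(recording(matrix(1:4, 2), 160, c("a", "a")), "unique")
})

test_that("Welch PSD localizes a pure tone and nulls a DC signal", {
  fs <- 160; t <- (0:9599) / fs
  rec <- recording(matrix(sin(2 * pi * 10 * t), nrow = 1), fs)
  p <- welch_psd(segment_recording(rec, 5), c(1, 40))
  expect_equal(p$freqs[which.max(p$psd[1, 1, ])], 10)
  # amplitude-2 tone carries power A^2/2 = 2 in the band
  rec2 <- recording(matrix(2 * sin(2 * pi * 10 * t), nrow = 1), fs)
  p2 <- welch_psd(segment_recording(rec2, 5), c(1, 40))
  df <- diff(p2$freqs[1:2])
  expect_equal(sum(p2$psd[1, 1, ]) * df, 2, tolerance = 1e-6)

  dc <- recording(matrix(rep(3.7, 9600), nrow = 1), fs)
  pdc <- welch_psd(segment_recording(dc, 5), c(1, 40))
  expect_true(all(pdc$psd < 1e-20))
})

test_that("Welch PSD of white noise is flat at sigma^2/(fs/2) per Hz", {
  set.seed(11)
  fs <- 160; n_epochs <- 100
  rec <- recording(matrix(rnorm(n_epochs * fs), nrow = 1), fs)
  # start one full Hann main-lobe width (2 bins = 4 Hz here) above DC:
  # segment-mean removal nulls the DC component, whose window main lobe
  # leaks a deterministic dip into the immediately adjacent bin
  p <- welch_psd(segment_recording(rec, 1), c(4, 40),
                 welch_config(window_s = 0.5))
  per_bin <- p$psd[, 1, ]                       # epochs x bins
  level <- 1 / (fs / 2)
  mc_se <- apply(per_bin, 2, sd) / sqrt(n_epochs)
  expect_true(all(abs(colMeans(per_bin) - level) < 3 * mc_se))
})

test_that("Welch PSD rejects impossible configurations", {
  rec <- recording(matrix(rnorm(2 * 1600), nrow = 2), fs = 160)
  ep <- segment_recording(rec, 5)
  expect_error(welch_psd(ep, c(1, 100)), "Nyquist")
  expect_error(welch_psd(ep, c(1, 40), welch_config(window_s = 10)),
               "longer than epoch")
  expect_error(welch_psd(ep, c(40, 1)), "f_min < f_max")
})

test_that("Spearman similarity is rank-invariant and matches the brute-force oracle", {
  set.seed(5)
  base <- matrix(abs(rnorm(4 * 20)) + 0.1, nrow = 4)      # 4 epochs x 20 bins
  psd <- array(0, dim = c(4, 1, 20))
  psd[1, 1, ] <- base[1, ]
  psd[2, 1, ] <- exp(base[1, ])                            # monotone transform
  psd[3, 1, ] <- max(base[1, ]) + min(base[1, ]) - base[1, ]  # reversed ranks
  psd[4, 1, ] <- base[4, ]
  s <- spearman_similarity(make_psd_set(psd, seq_len(20)), 1)
  expect_equal(s[1, 2], 1)
  expect_equal(s[1, 3], -1)
  expect_equal(s, t(s))
  expect_equal(diag(s), rep(1, 4))

  # classical mid-rank formula on vectors with ties
  x <- c(1, 2, 2, 4); y <- c(3, 1, 1, 2)
  psd2 <- array(0, dim = c(2, 1, 4)); psd2[1, 1, ] <- x; psd2[2, 1, ] <- y
  s2 <- spearman_similarity(make_psd_set(psd2, 1:4), 1)
  expect_equal(s2[1, 2], oracle_spearman(x, y), tolerance = 1e-12)

  # randomized cross-check against the oracle
  for (rep in 1:5) {
    psd3 <- array(sample(1:5, 3 * 1 * 12, replace = TRUE) + runif(36),
                  dim = c(3, 1, 12))
    s3 <- spearman_similarity(make_psd_set(psd3, 1:12), 1)
    for (i in 1:3) for (j in 1:3) {
      expect_equal(s3[i, j],
                   if (i == j) 1 else oracle_spearman(psd3[i, 1, ], psd3[j, 1, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("a constant spectrum raises a degenerate-spectrum error naming epoch and channel", {
  psd <- array(runif(3 * 2 * 10) + 0.5, dim = c(3, 2, 10))
  psd[2, 2, ] <- 1
  ps <- make_psd_set(psd, 1:10)
  expect_silent(spearman_similarity(ps, 1))
  expect_error(spearman_similarity(ps, 2), "epoch 2, channel 2")
})

test_that("score vectors: closed forms and diagonal-convention invariance", {
  expect_equal(channel_score_vector(matrix(1, 12, 12)), rep(1, 12))

  rho <- 0.42
  s2 <- matrix(c(1, rho, rho, 1), 2)
  expect_equal(channel_score_vector(s2), rep((1 + rho) / 2, 2))

  set.seed(9)
  m <- matrix(runif(36, -1, 1), 6); m <- (m + t(m)) / 2; diag(m) <- 1
  with_diag <- channel_score_vector(m)
  without_diag <- (rowSums(m) - 1) / 5
  expect_equal(order(-with_diag), order(-without_diag))
  expect_equal(with_diag, (5 * without_diag + 1) / 6)      # affine relation

  expect_error(channel_score_vector(matrix(1, 2, 3)), "square")
})

test_that("aggregation is an unweighted channel mean", {
  v <- runif(6)
  expect_equal(aggregate_scores(matrix(v, nrow = 1)), v)
  expect_equal(aggregate_scores(rbind(v, -v)), rep(0, 6))
  expect_equal(aggregate_scores(rbind(v, v)), v)
})

test_that("ranking is a stable descending sort with index tie-breaks", {
  expect_equal(rank_epochs(c(0.2, 0.9, 0.5)), c(2L, 3L, 1L))
  expect_equal(rank_epochs(rep(0.5, 5)), 1:5)
  expect_error(rank_epochs(c(1, NaN)), "non-finite")

  set.seed(21)
  s <- runif(12)
  top4 <- sort(rank_epochs(s)[1:4])
  combos <- enumerate_combinations(12, 4)
  best <- combos[which.max(apply(combos, 1, function(ix) sum(s[ix]))), ]
  expect_equal(top4, as.integer(best))                     # brute-force oracle
})

test_that("identical epochs score exactly 1 and scaling/permutation behave", {
  rec <- tiled_recording(12, 3)
  sc <- score_epochs(rec, 5)
  expect_identical(sc$scores, rep(1, 12))
  expect_equal(sc$ranking, 1:12)

  set.seed(2)
  rec2 <- recording(matrix(rnorm(3 * 9600), nrow = 3), fs = 160)
  sc2 <- score_epochs(rec2, 5)
  scaled <- recording(rec2$data * c(0.5, 3, 1700), 160)    # per-channel gains
  expect_identical(score_epochs(scaled, 5)$scores, sc2$scores)

  perm <- c(4, 1, 12, 7, 2, 11, 3, 10, 5, 9, 6, 8)
  scp <- score_epochs(permute_epochs(rec2, 5, perm), 5)
  expect_equal(scp$scores, sc2$scores[perm], tolerance = 1e-12)

  expect_true(all(sc2$scores >= -1 & sc2$scores <= 1))
  for (c in 1:3) {
    sl <- sc2$similarity[c, , ]
    expect_equal(sl, t(sl))
    expect_equal(diag(sl), rep(1, 12))
  }
})

test_that("pipeline matches the naive loop-based oracle within 1e-12", {
  set.seed(33)
  for (rep in 1:3) {
    rec <- recording(matrix(rnorm(3 * 160 * 12), nrow = 3), fs = 160)
    sc <- score_epochs(rec, 2, c(1, 40))                  # 6 epochs x 3 ch x 40 bins
    psd <- welch_psd(segment_recording(rec, 2), c(1, 40))$psd
    expect_equal(sc$scores, oracle_scores_from_psd(psd), tolerance = 1e-12)
  }
})

test_that("monotone per-channel PSD transforms leave scores unchanged", {
  set.seed(4)
  psd <- array(abs(rnorm(5 * 2 * 30)) + 0.1, dim = c(5, 2, 30))
  ps <- make_psd_set(psd, seq_len(30))
  base <- oracle_scores_from_psd(psd)
  sims <- function(ps) sapply(1:2, function(c) channel_score_vector(spearman_similarity(ps, c)))
  s1 <- aggregate_scores(t(sims(ps)))
  psd2 <- psd
  psd2[, 1, ] <- log(psd[, 1, ] + 1)                       # monotone, channel 1
  psd2[, 2, ] <- psd[, 2, ]^3                              # monotone, channel 2
  s2 <- aggregate_scores(t(sims(make_psd_set(psd2, seq_len(30)))))
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_equal(s1, base, tolerance = 1e-12)
})

test_that("stage errors are tagged with the failing stage", {
  short <- recording(matrix(rnorm(100), nrow = 1), fs = 160)
  expect_error(score_epochs(short, 5), "\\[segment\\]")
  rec <- recording(matrix(rnorm(1600), nrow = 1), fs = 160)
  expect_error(score_epochs(rec, 5, freq_range = c(1, 120)), "\\[welch_psd\\]")
})

test_that("degenerate epochs can be ranked last on request", {
  rec <- tiled_recording(6, 2)
  data <- rec$data
  data[, 1601:2400] <- 5                                   # epoch 3 constant
  flat <- recording(data, 160)
  expect_error(score_epochs(flat, 5), "degenerate")
  sc <- score_epochs(flat, 5, on_degenerate = "rank_last")
  expect_equal(tail(sc$ranking, 1), 3L)
  expect_identical(sc$scores[3], -Inf)
  expect_equal(sc$degenerate_epochs, 3L)
})
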