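# Synthetic EEG generator: determinism, analytic background spectrum,
# ground-truth artifact sensitivity, and cohort construction.

test_that("generation is bit-identical under a fixed seed", {
  spec <- synthetic_spec(n_channels = 3, duration_s = 20,
                         artifact_plan = list(list(epoch = 2, kind = "line_spike",
                                                   amplitude = 20)))
  a <- generate_recording(spec, seed = 123)
  b <- generate_recording(spec, seed = 123)
  expect_identical(a$recording$data, b$recording$data)
  c <- generate_recording(spec, seed = 124)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("spec validation catches bad artifact plans", {
  expect_error(synthetic_spec(duration_s = 60, artifact_plan =
    list(list(epoch = 13, kind = "broadband_burst", amplitude = 1))),
    "out of range")
  expect_error(synthetic_spec(artifact_plan =
    list(list(epoch = 1, kind = "blink", amplitude = 1))), "unknown artifact kind")
  expect_error(synthetic_spec(alpha_decay_per_epoch = 0))
  expect_error(generate_recording(synthetic_spec()), "seed")
})

test_that("alpha-free background matches the analytic 1/f alpha share", {
  # Discrete analytic oracle on the 1 Hz Welch grid: sum of f^-1 over 8..13
  # divided by the sum over 1..40. The 0.02 allowance covers the systematic
  # spectral-leakage bias of the windowed estimator near the 1/f pole.
  expected <- sum(1 / (8:13)) / sum(1 / (1:40))
  vals <- vapply(0:49, function(s) {
    g <- generate_recording(synthetic_spec(n_channels = 2, duration_s = 30,
                                           alpha_amplitude = 0), seed = s)
    mean(relative_band_power(
      welch_psd(segment_recording(g$recording, 5), c(1, 40)),
      alpha_band())$per_epoch_global)
  }, 0)
  expect_lt(abs(mean(vals) - expected), 0.02)
})

test_that("programmed alpha decay shows up in the per-epoch ground truth and features", {
  g <- generate_recording(synthetic_spec(n_channels = 4, alpha_amplitude = 10,
                                         alpha_decay_per_epoch = 0.9), seed = 5)
  expect_equal(g$truth$epoch_alpha_amplitude, 10 * 0.9^(0:11))
  ra <- relative_band_power(welch_psd(segment_recording(g$recording, 5), c(1, 40)),
                            alpha_band())$per_epoch_global
  expect_lt(cor(seq_along(ra), ra, method = "spearman"), 0)
})

test_that("a broadband burst epoch is scored last (fixed 20-seed battery)", {
  hits <- 0L
  for (seed in 0:19) {
    spec <- synthetic_spec(artifact_plan = list(list(epoch = 7,
      kind = "broadband_burst", amplitude = 50)))
    g <- generate_recording(spec, seed = seed)
    sc <- score_epochs(g$recording, 5)
    if (tail(sc$ranking, 1) == 7L) hits <- hits + 1L
    expect_lt(mean(sc$scores[7]), mean(sc$scores[-7]))   # artifact below clean mean
  }
  expect_gte(hits, 19L)
})

test_that("all three artifact archetypes depress the epoch score", {
  for (kind in c("broadband_burst", "low_freq_drift", "line_spike")) {
    spec <- synthetic_spec(n_channels = 4, duration_s = 30,
                           artifact_plan = list(list(epoch = 3, kind = kind,
                                                     amplitude = 80)))
    g <- generate_recording(spec, seed = 11)
    sc <- score_epochs(g$recording, 5)
    expect_equal(g$truth$labels[3], "artifact")
    expect_lt(sc$scores[3], max(sc$scores[-3]))
  }
})

test_that("cohorts share acquisition parameters and preserve the EC/EO ratio", {
  coh <- generate_cohort(n_subjects = 3,
                         eo_spec = synthetic_spec(n_channels = 2, duration_s = 20),
                         between_subject_sd = 0, seed = 9)
  expect_length(coh$subjects, 3)
  for (s in coh$subjects) {
    expect_equal(s$truth$subject_factor, 1)              # sd = 0: no jitter
    expect_equal(s$truth$ec$epoch_alpha_amplitude,
                 2 * s$truth$eo$epoch_alpha_amplitude)   # default ratio 2x
    expect_equal(nrow(s$eo$data), nrow(s$ec$data))
    expect_equal(s$eo$fs, s$ec$fs)
  }
  expect_error(generate_cohort(0), "positive")
  expect_error(generate_cohort(2, synthetic_spec(fs = 160),
                               synthetic_spec(fs = 200)), "agree on fs")
})

test_that("a no-effect cohort (ratio 1x) gives sweep d centered on zero", {
  # full 0-19 seed battery: the per-seed mean-d values are noisy and heavily
  # correlated across combos, so the check needs the whole battery
  means <- vapply(0:19, function(s) {
    coh <- generate_cohort(n_subjects = 10,
                           eo_spec = synthetic_spec(n_channels = 4, duration_s = 60),
                           ec_eo_ratio = 1, seed = s)
    feats <- cohort_features(coh, with_rankings = FALSE)
    mean(selection_sweep(feats, k = 4)$d_values)
  }, 0)
  expect_lt(abs(mean(means)), 2 * sd(means) / sqrt(length(means)))
})
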