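# Synthetic resting-state EEG with known ground truth: a 1/f^beta Gaussian
# background (spectral shaping of white noise), an alpha-band sinusoid whose
# amplitude can differ between conditions and decay across epochs (vigilance
# drift), and injectable epoch-localized artifacts. Everything is reproducible
# from a single integer seed (R's default Mersenne-Twister RNG).

#' Specify a synthetic resting-state EEG recording
#'
#' @param n_channels number of channels (default 16).
#' @param fs sampling rate, Hz (default 160).
#' @param duration_s recording length, seconds (default 60).
#' @param epoch_length_s epoch length used to localize per-epoch amplitudes and
#'   artifacts, seconds (default 5).
#' @param background_exponent beta of the 1/f^beta background power spectrum
#'   (default 1).
#' @param background_rms RMS amplitude of the background per channel,
#'   microvolts (default 10).
#' @param alpha_freq alpha oscillation frequency, Hz (default 10).
#' @param alpha_amplitude alpha sinusoid amplitude, microvolts (default 5).
#' @param alpha_decay_per_epoch multiplicative amplitude factor per epoch in
#'   (0, 1]; models drowsiness drift (default 1 = no drift).
#' @param artifact_plan list of \code{list(epoch =, kind =, amplitude =)}
#'   entries; \code{kind} is one of \code{"broadband_burst"},
#'   \code{"low_freq_drift"}, \code{"line_spike"}; amplitudes in microvolts.
#' @param seed default integer seed used by \code{\link{generate_recording}}.
#' @return A \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_channels = 16, fs = 160, duration_s = 60,
                           epoch_length_s = 5,
                           background_exponent = 1, background_rms = 10,
                           alpha_freq = 10, alpha_amplitude = 5,
                           alpha_decay_per_epoch = 1,
                           artifact_plan = list(), seed = NULL) {
  stopifnot(n_channels >= 1, fs > 0, duration_s > 0, epoch_length_s > 0,
            background_rms >= 0, alpha_amplitude >= 0,
            alpha_decay_per_epoch > 0, alpha_decay_per_epoch <= 1)
  n_epochs <- floor(duration_s / epoch_length_s)
  for (a in artifact_plan) {
    if (!all(c("epoch", "kind", "amplitude") %in% names(a)))
      stop("each artifact_plan entry needs `epoch`, `kind`, `amplitude`")
    if (a$epoch < 1 || a$epoch > n_epochs)
      stop(sprintf("artifact epoch %d out of range 1..%d", a$epoch, n_epochs))
    if (!a$kind %in% c("broadband_burst", "low_freq_drift", "line_spike"))
      stop("unknown artifact kind: ", a$kind)
    if (a$amplitude < 0) stop("artifact amplitude must be >= 0")
  }
  structure(
    list(n_channels = as.integer(n_channels), fs = fs, duration_s = duration_s,
         epoch_length_s = epoch_length_s,
         background_exponent = background_exponent,
         background_rms = background_rms,
         alpha_freq = alpha_freq, alpha_amplitude = alpha_amplitude,
         alpha_decay_per_epoch = alpha_decay_per_epoch,
         artifact_plan = artifact_plan, seed = seed),
    class = "synthetic_spec"
  )
}

# 1/f^(beta) power background: shape the spectrum of white Gaussian noise by
# f^(-beta/2) in amplitude (DC zeroed), then rescale each channel to the
# target RMS. Columns = channels; one FFT pass for all of them.
shaped_background <- function(n, n_ch, fs, beta, rms) {
  x <- matrix(stats::rnorm(n * n_ch), nrow = n)
  if (rms == 0) return(x * 0)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)                 # |frequency| of each DFT bin
  s <- c(0, f[-1L]^(-beta / 2))
  y <- Re(stats::mvfft(stats::mvfft(x) * s, inverse = TRUE)) / n
  sweep(y, 2L, rms / sqrt(colMeans(y^2)), `*`)
}

#' Generate a synthetic recording with ground truth
#'
#' Each channel is the sum of a 1/f^beta Gaussian background, an alpha
#' sinusoid with channel-specific random phase and per-epoch amplitude
#' \code{alpha_amplitude * alpha_decay_per_epoch^(epoch - 1)}, and any
#' artifacts in the plan (injected into every channel of the target epoch).
#' Identical spec and seed give bit-identical output.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param seed integer seed; defaults to \code{spec$seed}.
#' @return list with \code{recording} (an \code{\link{recording}}) and
#'   \code{truth}: per-epoch alpha amplitudes, artifact epochs, and a
#'   clean/artifact label per epoch.
#' @examples
#' spec <- synthetic_spec(n_channels = 2, duration_s = 20)
#' out <- generate_recording(spec, seed = 1)
#' out$truth$labels
#' @export
generate_recording <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(seed)) stop("a seed is required (set it in the spec or pass `seed`)")
  set.seed(as.integer(seed))
  n <- round(spec$fs * spec$duration_s)
  spe <- floor(spec$epoch_length_s * spec$fs)
  n_epochs <- n %/% spe
  t <- (seq_len(n) - 1L) / spec$fs

  # per-sample alpha amplitude, stepwise per epoch (tail keeps the last value)
  ep_of_sample <- pmin(((seq_len(n) - 1L) %/% spe) + 1L, n_epochs)
  amp_per_epoch <- spec$alpha_amplitude * spec$alpha_decay_per_epoch^(seq_len(n_epochs) - 1L)
  amp <- amp_per_epoch[ep_of_sample]

  bg <- shaped_background(n, spec$n_channels, spec$fs,
                          spec$background_exponent, spec$background_rms)
  phi <- stats::runif(spec$n_channels, 0, 2 * pi)
  osc <- outer(2 * pi * spec$alpha_freq * t, phi, `+`)
  data <- t(bg + (amp * sin(osc)))
  artifact_epochs <- integer(0)
  for (a in spec$artifact_plan) {
    idx <- ((a$epoch - 1L) * spe + 1L):(a$epoch * spe)
    tt <- t[idx]
    add <- switch(a$kind,
      broadband_burst = matrix(stats::rnorm(spec$n_channels * spe, sd = a$amplitude),
                               nrow = spec$n_channels),
      low_freq_drift  = matrix(rep(a$amplitude * sin(2 * pi * 0.3 * (tt - tt[1L])),
                                   each = spec$n_channels),
                               nrow = spec$n_channels),
      line_spike      = matrix(rep(a$amplitude * sin(2 * pi * 50 * (tt - tt[1L])),
                                   each = spec$n_channels),
                               nrow = spec$n_channels))
    data[, idx] <- data[, idx] + add
    artifact_epochs <- union(artifact_epochs, a$epoch)
  }
  labels <- rep("clean", n_epochs)
  labels[artifact_epochs] <- "artifact"
  list(
    recording = recording(data, spec$fs),
    truth = list(epoch_alpha_amplitude = amp_per_epoch,
                 artifact_epochs = sort(as.integer(artifact_epochs)),
                 labels = labels, seed = as.integer(seed))
  )
}

#' Generate a paired eyes-open / eyes-closed cohort
#'
#' Subjects share the acquisition parameters of the two specs (which must
#' agree on fs, channels and duration) and differ by a log-normal jitter of
#' their alpha amplitudes (the same subject factor applied to both conditions,
#' so the programmed EC/EO ratio is preserved) and by independent noise and
#' phase realizations. By default the EC spec is the EO spec with twice the
#' alpha amplitude.
#'
#' @param n_subjects number of subjects (default 30).
#' @param eo_spec \code{\link{synthetic_spec}} for the eyes-open run.
#' @param ec_spec spec for the eyes-closed run; default: \code{eo_spec} with
#'   \code{alpha_amplitude * ec_eo_ratio}.
#' @param ec_eo_ratio EC/EO alpha amplitude ratio used when \code{ec_spec} is
#'   NULL (default 2).
#' @param between_subject_sd standard deviation of the log-normal
#'   between-subject amplitude factor (default 0.2).
#' @param seed integer seed for the whole cohort.
#' @return An object of class \code{synthetic_cohort}: list of subjects, each
#'   \code{list(subject_id, eo, ec, truth)} where \code{eo}/\code{ec} are
#'   recordings and \code{truth} holds both runs' ground truth and the subject
#'   amplitude factor.
#' @export
generate_cohort <- function(n_subjects = 30, eo_spec = synthetic_spec(),
                            ec_spec = NULL, ec_eo_ratio = 2,
                            between_subject_sd = 0.2, seed = 1) {
  if (n_subjects < 1L) stop("`n_subjects` must be positive")
  if (is.null(ec_spec)) {
    ec_spec <- eo_spec
    ec_spec$alpha_amplitude <- eo_spec$alpha_amplitude * ec_eo_ratio
  }
  for (f in c("fs", "n_channels", "duration_s", "epoch_length_s")) {
    if (!identical(eo_spec[[f]], ec_spec[[f]]))
      stop("eo_spec and ec_spec must agree on ", f)
  }
  set.seed(as.integer(seed))
  # pre-draw subject factors and per-run seeds so subjects are independent
  factors <- exp(stats::rnorm(n_subjects, 0, between_subject_sd))
  run_seeds <- sample.int(.Machine$integer.max, 2L * n_subjects)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    eo_i <- eo_spec; eo_i$alpha_amplitude <- eo_spec$alpha_amplitude * factors[i]
    ec_i <- ec_spec; ec_i$alpha_amplitude <- ec_spec$alpha_amplitude * factors[i]
    eo <- generate_recording(eo_i, seed = run_seeds[2L * i - 1L])
    ec <- generate_recording(ec_i, seed = run_seeds[2L * i])
    subjects[[i]] <- list(
      subject_id = sprintf("S%03d", i),
      eo = eo$recording, ec = ec$recording,
      truth = list(subject_factor = factors[i], eo = eo$truth, ec = ec$truth)
    )
  }
  structure(list(subjects = subjects,
                 eo_spec = eo_spec, ec_spec = ec_spec,
                 between_subject_sd = between_subject_sd, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' Per-subject features (and rankings) from a synthetic cohort
#'
#' Computes, for every subject and both runs, the per-epoch global feature
#' (relative alpha power or global PLI) and the epoch ranking from
#' \code{\link{score_epochs}}, ready for \code{\link{selection_sweep}}.
#'
#' @param cohort a \code{\link{generate_cohort}} result (or any list of
#'   subjects shaped the same way).
#' @param feature \code{"alpha"} (relative alpha power) or \code{"pli"}.
#' @param epoch_length_s epoch length, seconds.
#' @param freq_range PSD range, Hz.
#' @param band feature band (default alpha 8-13 Hz).
#' @param with_rankings if TRUE (default), run the epoch scorer on each run to
#'   obtain rankings; set FALSE to skip the scorer when only sweep d values
#'   are needed.
#' @return list of \code{\link{subject_features}}.
#' @export
cohort_features <- function(cohort, feature = c("alpha", "pli"),
                            epoch_length_s = 5, freq_range = c(1, 40),
                            band = alpha_band(), with_rankings = TRUE) {
  feature <- match.arg(feature)
  one_run <- function(rec) {
    if (feature == "alpha") {
      psd <- welch_psd(segment_recording(rec, epoch_length_s), freq_range)
      relative_band_power(psd, band)$per_epoch_global
    } else {
      pli_epochs(rec, epoch_length_s, band)
    }
  }
  lapply(cohort$subjects, function(s) {
    eo_rank <- ec_rank <- NULL
    if (with_rankings) {
      eo_rank <- score_epochs(s$eo, epoch_length_s, freq_range)$ranking
      ec_rank <- score_epochs(s$ec, epoch_length_s, freq_range)$ranking
    }
    subject_features(s$subject_id, one_run(s$eo), one_run(s$ec), eo_rank, ec_rank)
  })
}
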