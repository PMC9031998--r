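# Minimal EDF/EDF+ support (continuous recordings, 16-bit samples). Only what
# the pipeline needs: reading multichannel signals in physical units with
# channel selection, and writing synthetic recordings so the full CLI path is
# exercisable offline. No signal may be lost silently: non-finite samples and
# mixed sampling rates are hard errors.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)  # left-justified, space padded
}

edf_num <- function(x, width) edf_pad(format(x, trim = TRUE, scientific = FALSE), width)

#' Write a recording to an EDF file
#'
#' 16-bit EDF with one-second data records; the physical range of each channel
#' is mapped onto the full digital range -32768..32767, so the round-trip
#' error is bounded by half a quantization step of each channel's amplitude
#' range. Requires an integer sampling rate (a limitation of the one-second
#' record layout). The header carries a fixed start date/time so identical
#' inputs produce byte-identical files.
#'
#' @param rec an \code{\link{recording}}.
#' @param path output file path.
#' @param patient,recording_id free-text header fields.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "epochscore") {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate (one-second records)")
  spr <- as.integer(round(fs))
  n_ch <- nrow(rec$data)
  n_records <- ncol(rec$data) %/% spr
  if (n_records < 1L) stop("recording shorter than one EDF record (1 s)")
  used <- rec$data[, seq_len(n_records * spr), drop = FALSE]

  # integer physical bounds: always exactly representable in the 8-char
  # header field, and never clip the data
  pmin <- floor(apply(used, 1L, min))
  pmax <- ceiling(apply(used, 1L, max))
  flat <- pmax - pmin < 1
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  if (any(abs(c(pmin, pmax)) >= 1e7))
    stop("amplitudes too large for the EDF header's 8-character range fields")
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * n_ch
  header <- paste0(
    edf_pad("0", 8), edf_pad(patient, 80), edf_pad(recording_id, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_num(hdr_bytes, 8), edf_pad("", 44),
    edf_num(n_records, 8), edf_num(1, 8), edf_num(n_ch, 4))
  sig_field <- function(values, width)
    paste(vapply(values, edf_pad, "", width = width), collapse = "")
  header <- paste0(header,
    sig_field(rec$channel_labels, 16),
    sig_field(rep("", n_ch), 80),
    sig_field(rep("uV", n_ch), 8),
    sig_field(format(pmin, trim = TRUE, scientific = FALSE), 8),
    sig_field(format(pmax, trim = TRUE, scientific = FALSE), 8),
    sig_field(rep(dmin, n_ch), 8),
    sig_field(rep(dmax, n_ch), 8),
    sig_field(rep("", n_ch), 80),
    sig_field(rep(spr, n_ch), 8),
    sig_field(rep("", n_ch), 32))
  writeChar(header, con, eos = NULL)

  gain <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_records)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    block <- matrix(0L, nrow = spr, ncol = n_ch)
    for (c in seq_len(n_ch)) {
      dig <- round((used[c, idx] - pmin[c]) * gain[c]) + dmin
      block[, c] <- as.integer(pmin(pmax(dig, dmin), dmax))
    }
    writeBin(as.vector(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF/EDF+ file into a recording
#'
#' Signals are returned in physical units (assumed microvolts; millivolt and
#' volt dimensions are converted). EDF+ annotation channels are dropped. If the
#' remaining signals have heterogeneous sampling rates, a channel selection
#' restricted to a single rate is required. Non-finite samples are rejected.
#'
#' @param path EDF file path.
#' @param channels optional character vector of channel labels to keep, in the
#'   given order (a missing label is an error naming the available ones).
#' @return an \code{\link{recording}}.
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd_s <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd_s(8); rd_s(80); rd_s(80); rd_s(8); rd_s(8)
  rd_s(8)  # header bytes
  rd_s(44)
  n_records <- as.integer(rd_s(8))
  rec_dur <- as.numeric(rd_s(8))
  n_sig <- as.integer(rd_s(4))
  if (is.na(n_sig) || n_sig < 1L) stop("not a valid EDF file: ", path)

  fld <- function(w) vapply(seq_len(n_sig), function(i) rd_s(w), "")
  labels <- fld(16); fld(80)
  dims <- fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)

  is_annot <- grepl("EDF Annotations", labels, fixed = TRUE)
  raw <- readBin(con, "integer", n = n_records * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_records * sum(spr))
    stop("EDF file truncated: ", path)

  offsets <- c(0L, cumsum(spr))
  rec_len <- sum(spr)
  sig_data <- function(i) {
    starts <- (seq_len(n_records) - 1L) * rec_len + offsets[i]
    idx <- as.vector(outer(seq_len(spr[i]), starts, `+`))
    dig <- raw[idx]
    phys <- (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) + pmin[i]
    unit <- tolower(dims[i])
    if (unit %in% c("mv")) phys <- phys * 1e3
    if (unit %in% c("v")) phys <- phys * 1e6
    phys
  }

  avail <- labels[!is_annot]
  if (is.null(channels)) {
    pick <- which(!is_annot)
    if (length(unique(spr[pick])) > 1L)
      stop("mixed sampling rates (", paste(unique(spr[pick] / rec_dur), collapse = ", "),
           " Hz); pass `channels` restricted to one rate")
  } else {
    missing <- setdiff(channels, avail)
    if (length(missing))
      stop("channel(s) not found: ", paste(missing, collapse = ", "),
           "; available: ", paste(avail, collapse = ", "))
    pick <- match(channels, labels)
    if (length(unique(spr[pick])) > 1L)
      stop("selected channels have mixed sampling rates")
  }
  if (!length(pick)) stop("no data channels in EDF file: ", path)
  fs <- spr[pick[1L]] / rec_dur
  data <- t(vapply(pick, sig_data, numeric(n_records * spr[pick[1L]])))
  if (!all(is.finite(data)))
    stop("EDF file contains non-finite values after calibration: ", path)
  recording(data, fs, labels[pick])
}
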