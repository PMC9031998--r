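# Delimited-text ingestion and report serialization.

#' Read a delimited numeric matrix as a recording
#'
#' Accepts comma-, tab- or whitespace-separated rectangular numeric tables
#' (delimiter auto-detected from the first line). Non-numeric or non-finite
#' cells are errors naming the offending row and column. Channel labels are
#' synthesized.
#'
#' @param path file path.
#' @param fs sampling rate in Hz.
#' @param orientation \code{"channels_in_rows"} (default) or
#'   \code{"channels_in_columns"}.
#' @return an \code{\link{recording}}.
#' @export
read_delimited <- function(path, fs,
                           orientation = c("channels_in_rows", "channels_in_columns")) {
  orientation <- match.arg(orientation)
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty file: ", path)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else
         if (grepl("\t", first, fixed = TRUE)) "\t" else ""
  tab <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE,
                      colClasses = "character", strip.white = TRUE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  m <- suppressWarnings(matrix(as.numeric(as.matrix(tab)),
                               nrow = nrow(tab), ncol = ncol(tab)))
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or non-finite value at row %d, column %d of %s ('%s')",
                 bad[1, 1], bad[1, 2], path, as.matrix(tab)[bad[1, 1], bad[1, 2]]))
  }
  if (orientation == "channels_in_columns") m <- t(m)
  recording(m, fs)
}

#' Assemble a serializable score report
#'
#' Bundles per-epoch scores, the descending ranking (both 1-based, the package
#' convention, and 0-based for interoperability), the suggested top-k epochs,
#' the configuration used, and input provenance.
#'
#' @param result an \code{\link{score_epochs}} result.
#' @param top_k how many suggested epochs to list (default 4).
#' @param input provenance string (file path or description).
#' @return a named list (class \code{score_report}) that round-trips through
#'   JSON.
#' @export
score_report <- function(result, top_k = 4, input = "<in-memory>") {
  stopifnot(inherits(result, "epoch_scores"))
  top_k <- min(top_k, result$n_epochs)
  cfg <- result$welch_cfg
  structure(list(
    tool = "epochscore",
    version = as.character(utils::packageVersion("epochscore")),
    input = input,
    fs = result$fs,
    channels = result$channel_labels,
    epoch_length_s = result$epoch_length_s,
    freq_range = result$freq_range,
    welch = list(window_s = if (is.null(cfg$window_s)) "auto" else cfg$window_s,
                 overlap_fraction = cfg$overlap_fraction,
                 window_shape = cfg$window_shape),
    n_epochs = result$n_epochs,
    scores = as.numeric(result$scores),
    ranking = as.integer(result$ranking),
    ranking_0based = as.integer(result$ranking - 1L),
    suggested_epochs = as.integer(result$ranking[seq_len(top_k)]),
    degenerate_epochs = as.integer(result$degenerate_epochs)
  ), class = "score_report")
}

#' Write scoring and sweep results to disk
#'
#' Writes, into \code{out_dir}: \code{scores.csv} (1-based epoch index, score,
#' rank position), \code{score_report.json}, and -- when a sweep is supplied --
#' \code{sweep.json} (combos as 1-based tuples, d and t values, the
#' score-guided selection d and its percentile). JSON field order is fixed and
#' floats are serialized at 12 significant digits, so identical inputs give
#' byte-identical files.
#'
#' @param score_result an \code{\link{score_epochs}} result, or NULL.
#' @param sweep an \code{\link{selection_sweep}} result, or NULL.
#' @param out_dir output directory (created if needed).
#' @param top_k forwarded to \code{\link{score_report}}.
#' @param input provenance string.
#' @return character vector of the files written, invisibly.
#' @export
write_reports <- function(score_result = NULL, sweep = NULL, out_dir,
                          top_k = 4, input = "<in-memory>") {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  written <- character(0)
  if (!is.null(score_result)) {
    stopifnot(inherits(score_result, "epoch_scores"))
    rank_pos <- order(score_result$ranking)   # position of each epoch in the ranking
    tab <- data.frame(epoch = seq_len(score_result$n_epochs),
                      score = sprintf("%.12g", score_result$scores),
                      rank = rank_pos)
    f <- file.path(out_dir, "scores.csv")
    utils::write.csv(tab, f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
    rep <- score_report(score_result, top_k = top_k, input = input)
    f <- file.path(out_dir, "score_report.json")
    jsonlite::write_json(unclass(rep), f, auto_unbox = TRUE, digits = 12, pretty = TRUE)
    written <- c(written, f)
  }
  if (!is.null(sweep)) {
    stopifnot(inherits(sweep, "effect_size_sweep"))
    payload <- list(
      tool = "epochscore",
      version = as.character(utils::packageVersion("epochscore")),
      k = sweep$k, n_epochs = sweep$n_epochs, n_subjects = sweep$n_subjects,
      combos = apply(sweep$combos, 1L, as.integer, simplify = FALSE),
      d_values = as.numeric(sweep$d_values),
      t_values = as.numeric(sweep$t_values),
      scorepochs_d = sweep$scorepochs_d,
      scorepochs_percentile = sweep$scorepochs_percentile)
    f <- file.path(out_dir, "sweep.json")
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = 12, pretty = TRUE)
    written <- c(written, f)
  }
  invisible(written)
}
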