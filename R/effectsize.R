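# Paired effect sizes and the exhaustive epoch-selection sweep: every k-subset
# of epochs is used (the same subset for all subjects and both conditions) to
# average a per-epoch global feature, and the paired Cohen's d across subjects
# is recorded, giving the distribution against which a score-guided selection
# is placed.

#' Paired Cohen's d
#'
#' \code{d = mean(x - y) / sd(x - y)} with the sample (n - 1) standard
#' deviation. Values are paired by position (subject).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return the effect size d.
#' @examples
#' paired_cohens_d(c(2, 4, 6), c(1, 2, 3))  # differences 1,2,3 -> d = 2
#' @export
paired_cohens_d <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length (paired)")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0)
    stop("zero variance of paired differences; Cohen's d undefined")
  mean(d) / s
}

#' Paired t test
#'
#' Classical two-sided paired t on the differences; \code{t = d * sqrt(n)}
#' where d is the paired Cohen's d.
#'
#' @param x,y numeric vectors of equal length >= 2, paired by position.
#' @return list with \code{t}, \code{p} (two-sided) and \code{df}.
#' @export
paired_t_test <- function(x, y) {
  d <- paired_cohens_d(x, y)
  n <- length(x)
  t <- d * sqrt(n)
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1)
}

#' Enumerate all k-subsets of n epochs in lexicographic order
#'
#' 1-based index tuples, ordered lexicographically: for n = 12, k = 4 the
#' first subsets are (1,2,3,4), (1,2,3,5), ... and the last is (9,10,11,12),
#' for 495 in total.
#'
#' @param n_epochs number of epochs.
#' @param k subset size, \code{1 <= k <= n_epochs}.
#' @return integer matrix, \code{choose(n_epochs, k)} rows x k columns.
#' @export
enumerate_combinations <- function(n_epochs, k) {
  if (k < 1L || k > n_epochs) stop("need 1 <= k <= n_epochs")
  m <- t(utils::combn(n_epochs, k))
  storage.mode(m) <- "integer"
  m
}

#' Empirical percentile of a value within a distribution
#'
#' \code{100 * (number of entries <= value) / size}.
#'
#' @param value a number.
#' @param distribution non-empty numeric vector.
#' @return percentile in [0, 100].
#' @export
percentile_of <- function(value, distribution) {
  if (length(distribution) < 1L) stop("`distribution` must be non-empty")
  100 * mean(distribution <= value)
}

#' Bundle one subject's per-epoch features and rankings
#'
#' @param subject_id identifier string.
#' @param eo,ec per-epoch global feature values (equal length) for the
#'   eyes-open and eyes-closed runs.
#' @param eo_ranking,ec_ranking optional 1-based epoch rankings (best first)
#'   from \code{\link{score_epochs}} of the corresponding run; required for
#'   the score-guided selection in \code{\link{selection_sweep}}.
#' @return A \code{subject_features} list.
#' @export
subject_features <- function(subject_id, eo, ec,
                             eo_ranking = NULL, ec_ranking = NULL) {
  if (length(eo) != length(ec))
    stop("`eo` and `ec` must have the same number of epochs")
  for (r in list(eo_ranking, ec_ranking)) {
    if (!is.null(r) && !identical(sort(as.integer(r)), seq_along(eo)))
      stop("rankings must be permutations of 1..n_epochs")
  }
  structure(list(subject_id = as.character(subject_id),
                 eo = as.numeric(eo), ec = as.numeric(ec),
                 eo_ranking = eo_ranking, ec_ranking = ec_ranking),
            class = "subject_features")
}

#' Exhaustive epoch-selection sweep with paired effect sizes
#'
#' For every k-subset of epochs (same subset for all subjects and both
#' conditions), averages each subject's per-epoch global feature over the
#' subset in the EO and EC runs, then computes the paired Cohen's d and t
#' statistic of the EC - EO contrast across subjects. If subjects carry
#' rankings, the score-guided selection (each subject's own top-k epochs,
#' per condition) is evaluated the same way and placed as a percentile within
#' the sweep's d distribution.
#'
#' @param features list of \code{\link{subject_features}}, all with the same
#'   number of epochs.
#' @param k number of epochs per selection (default 4).
#' @return An object of class \code{effect_size_sweep}: \code{combos} (matrix,
#'   lexicographic 1-based subsets), \code{d_values}, \code{t_values},
#'   \code{p_values}, \code{scorepochs_d}, \code{scorepochs_percentile},
#'   \code{k}, \code{n_subjects}, \code{n_epochs}.
#' @export
selection_sweep <- function(features, k = 4) {
  if (!length(features)) stop("`features` must be a non-empty list")
  n_epochs <- length(features[[1L]]$eo)
  for (s in features) {
    if (!inherits(s, "subject_features"))
      stop("every element of `features` must be a subject_features object")
    if (length(s$eo) != n_epochs)
      stop(sprintf("subject %s has %d epochs; expected %d",
                   s$subject_id, length(s$eo), n_epochs))
  }
  n_sub <- length(features)
  eo <- vapply(features, `[[`, numeric(n_epochs), "eo")   # n_epochs x n_sub
  ec <- vapply(features, `[[`, numeric(n_epochs), "ec")

  combos <- enumerate_combinations(n_epochs, k)
  sel <- matrix(0, nrow(combos), n_epochs)                # combo x epoch indicator
  sel[cbind(rep(seq_len(nrow(combos)), k), as.vector(combos))] <- 1 / k
  diff <- sel %*% ec - sel %*% eo                          # combo x subject
  mu <- rowMeans(diff)
  sdd <- sqrt(rowSums((diff - mu)^2) / (n_sub - 1))
  if (any(sdd == 0)) stop("zero variance of paired differences in at least one selection")
  d_values <- mu / sdd
  t_values <- d_values * sqrt(n_sub)
  p_values <- 2 * stats::pt(-abs(t_values), df = n_sub - 1)

  scorepochs_d <- NA_real_
  scorepochs_percentile <- NA_real_
  if (all(vapply(features, function(s) !is.null(s$eo_ranking) && !is.null(s$ec_ranking), TRUE))) {
    eo_sel <- vapply(features, function(s) mean(s$eo[s$eo_ranking[seq_len(k)]]), 0)
    ec_sel <- vapply(features, function(s) mean(s$ec[s$ec_ranking[seq_len(k)]]), 0)
    scorepochs_d <- paired_cohens_d(ec_sel, eo_sel)
    scorepochs_percentile <- percentile_of(scorepochs_d, d_values)
  }

  structure(
    list(combos = combos, d_values = d_values, t_values = t_values,
         p_values = p_values, scorepochs_d = scorepochs_d,
         scorepochs_percentile = scorepochs_percentile,
         k = as.integer(k), n_subjects = n_sub, n_epochs = n_epochs),
    class = "effect_size_sweep"
  )
}

#' @export
print.effect_size_sweep <- function(x, ...) {
  cat(sprintf("<effect_size_sweep> %d selections of %d/%d epochs, %d subjects\n",
              nrow(x$combos), x$k, x$n_epochs, x$n_subjects))
  cat(sprintf("d: min %.4f / mean %.4f / max %.4f\n",
              min(x$d_values), mean(x$d_values), max(x$d_values)))
  if (is.finite(x$scorepochs_d))
    cat(sprintf("score-guided selection: d = %.4f (percentile %.1f)\n",
                x$scorepochs_d, x$scorepochs_percentile))
  invisible(x)
}
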