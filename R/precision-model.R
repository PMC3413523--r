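# Power-law model relating consensus column support to alignment precision,
# plus score-threshold column filtering ("data selection").

#' Bin column observations by support score
#'
#' Groups (score, precision) observations into score bins of the given width.
#' Bins are half-open `[lower, upper)` and partition (0, 1], except the top
#' bin, which is closed so a perfect score of 1.0 is binnable. Observations
#' with undefined (`NA`) precision — columns holding fewer than two residues —
#' are dropped with a warning, as they carry no precision information.
#'
#' @param scores numeric vector of normalized column scores in (0, 1].
#' @param precisions numeric vector of column precisions in \[0, 1\]
#'   (`NA` = undefined).
#' @param width bin width in (0, 1]; default 0.1.
#' @return data.frame with one row per bin: `lower`, `upper`, `midpoint`,
#'   `n_columns`, `mean_precision` (NA for empty bins).
#' @export
bin_columns <- function(scores, precisions, width = 0.1) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0 || width > 1) {
    usage_abort("bin width must lie in (0, 1]")
  }
  if (length(scores) != length(precisions)) {
    usage_abort("scores and precisions differ in length")
  }
  keep <- !is.na(precisions)
  if (any(!keep)) {
    warning(sprintf("dropping %d observation(s) with undefined precision",
                    sum(!keep)), call. = FALSE)
    scores <- scores[keep]
    precisions <- precisions[keep]
  }
  if (length(scores) > 0L &&
      (any(scores <= 0 | scores > 1) ||
       any(precisions < 0 | precisions > 1))) {
    usage_abort("scores must lie in (0, 1] and precisions in [0, 1]")
  }
  nb <- ceiling(1 / width - 1e-9)
  lower <- (seq_len(nb) - 1L) * width
  upper <- pmin(lower + width, 1)
  # nudge before floor so boundary scores (0.3 / 0.1 = 2.999...96 in floating
  # point) land in the bin whose lower edge they sit on
  idx <- pmin(floor(scores / width + 1e-9) + 1L, nb)
  n_columns <- tabulate(idx, nbins = nb)
  mean_precision <- rep(NA_real_, nb)
  if (length(idx) > 0L) {
    means <- tapply(precisions, factor(idx, levels = seq_len(nb)), mean)
    mean_precision <- as.numeric(means)
  }
  data.frame(lower = lower, upper = upper, midpoint = lower + width / 2,
             n_columns = n_columns, mean_precision = mean_precision)
}

#' Fit a power-law score-to-precision model
#'
#' Fits `f(x) = x^m` to binned mean precisions by least squares: the residual
#' sum over non-empty bins of `(mean_precision - midpoint^m)^2` is minimized
#' over m by bounded one-dimensional search on (1e-6, 50]. Bin midpoints are
#' used as the abscissa (the symmetric choice). Empty bins are excluded; a
#' fit that lands on the search boundary (e.g. all precisions exactly 1, for
#' which any m -> 0 is equally good) is reported with a warning rather than
#' an error.
#'
#' @param bins data.frame from [bin_columns] (needs at least two non-empty
#'   bins).
#' @return object of class `power_model`: list with `m` (the exponent),
#'   `rss` (residual sum of squares) and `n_bins` (bins used).
#' @examples
#' b <- bin_columns(seq(0.05, 0.95, 0.1), seq(0.05, 0.95, 0.1)^0.5)
#' fit_power(b)$m
#' @export
fit_power <- function(bins) {
  if (!is.data.frame(bins) ||
      !all(c("midpoint", "n_columns", "mean_precision") %in% names(bins))) {
    usage_abort("bins must be a data.frame from bin_columns()")
  }
  use <- bins[bins$n_columns > 0L & !is.na(bins$mean_precision), ]
  if (nrow(use) < 2L) {
    msa_abort("fit_power needs at least two non-empty bins",
              "msamerge_too_few_bins")
  }
  rss <- function(m) sum((use$mean_precision - use$midpoint^m)^2)
  opt <- stats::optimize(rss, interval = c(1e-6, 50), tol = 1e-10)
  m <- opt$minimum
  if (m < 1e-4 || m > 49.5) {
    warning(sprintf("power-law fit is degenerate (m = %.3g at search boundary)",
                    m), call. = FALSE)
  }
  structure(list(m = m, rss = opt$objective, n_bins = nrow(use)),
            class = "power_model")
}

#' @export
print.power_model <- function(x, ...) {
  cat(sprintf("power-law precision model f(x) = x^m, m = %.4f (%d bins, RSS %.3g)\n",
              x$m, x$n_bins, x$rss))
  invisible(x)
}

#' Expected alignment error rate at a given column score
#'
#' Under the fitted model, a column with normalized support score x has
#' expected precision x^m, hence expected false-positive alignment error
#' rate `1 - x^m`. Decreasing in the score for fixed m > 0 and increasing in
#' m for a fixed score below 1.
#'
#' @param model a `power_model` from [fit_power], or a positive numeric
#'   exponent m.
#' @param score normalized column score(s) in (0, 1].
#' @return numeric expected error rate(s) in \[0, 1).
#' @examples
#' expected_error(0.124, c(0.92, 0.66))
#' @export
expected_error <- function(model, score) {
  m <- if (inherits(model, "power_model")) model$m else model
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0) {
    usage_abort("model must be a power_model or a positive exponent")
  }
  if (!is.numeric(score) || any(is.na(score)) ||
      any(score <= 0 | score > 1)) {
    usage_abort("score must lie in (0, 1]")
  }
  1 - score^m
}

#' Filter consensus columns by support score
#'
#' Data selection by column reliability: keeps exactly the columns whose
#' normalized support score is at least `min_score`, preserving column order
#' and the residue order within every sequence. All sequences are retained
#' even if they become all-gap (downstream phylogenetics expects a fixed
#' taxon set); newly all-gap columns cannot arise because whole columns are
#' removed. A threshold above the maximum score yields a zero-column
#' alignment, reported as such rather than as an error.
#'
#' @param result an `msa_consensus` from [merge_alignments].
#' @param min_score threshold in \[0, 1\] on the normalized score.
#' @return an [msa] holding the surviving columns.
#' @export
filter_columns <- function(result, min_score) {
  stopifnot(inherits(result, "msa_consensus"))
  if (!is.numeric(min_score) || length(min_score) != 1L ||
      is.na(min_score) || min_score < 0 || min_score > 1) {
    usage_abort("min_score must lie in [0, 1]")
  }
  keep <- result$normalized_scores >= min_score
  m <- msa_matrix(result$alignment)[, keep, drop = FALSE]
  matrix_to_msa(m, result$alignment$ids)
}
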