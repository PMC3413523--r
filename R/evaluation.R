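# Letter-pair evaluation of an inferred alignment against a reference.
#
# The unit of scoring is the aligned letter-pair: two residues from
# different sequences placed in the same column. A pair is identified by
# (id, ungapped position) of both residues, canonicalized so the smaller id
# comes first; a column holding r residues contributes r(r-1)/2 pairs.

# Per-column pair sets, as canonical strings. Internal workhorse for both
# whole-alignment and per-column scores.
column_pair_sets <- function(aln) {
  m <- msa_matrix(aln)
  cum <- (m != "-") * 1L
  if (ncol(cum) > 1L) cum <- t(apply(cum, 1L, cumsum))
  ids <- aln$ids
  out <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    r <- which(m[, j] != "-")
    if (length(r) < 2L) {
      out[[j]] <- character(0L)
      next
    }
    cb <- utils::combn(r, 2L)
    a <- cb[1L, ]
    b <- cb[2L, ]
    pa <- cum[cbind(a, j)]
    pb <- cum[cbind(b, j)]
    ia <- ids[a]
    ib <- ids[b]
    swap <- ia > ib
    out[[j]] <- paste(ifelse(swap, ib, ia), ifelse(swap, pb, pa),
                      ifelse(swap, ia, ib), ifelse(swap, pa, pb),
                      sep = "|")
  }
  out
}

#' Aligned letter-pairs of an alignment
#'
#' @param aln an [msa] object.
#' @return character vector of canonical pair identifiers
#'   `"idA|posA|idB|posB"` with 1-based ungapped positions; one entry per
#'   unordered pair of residues sharing a column. A residue occupies exactly
#'   one column, so the vector is duplicate-free.
#' @examples
#' aligned_pairs(msa(c("a", "b"), c("AC", "AC")))
#' @export
aligned_pairs <- function(aln) {
  unlist(column_pair_sets(aln), use.names = FALSE)
}

check_comparable <- function(inferred, reference) {
  stopifnot(inherits(inferred, "msa"), inherits(reference, "msa"))
  harmonize_alignments(list(inferred, reference))  # errors name offending ids
  invisible(NULL)
}

#' Compare an inferred alignment against a reference
#'
#' Counts true-positive (pairs in both), false-positive (pairs only in the
#' inferred alignment) and false-negative (pairs only in the reference)
#' aligned letter-pairs, and derives precision = TP/(TP+FP),
#' recall = TP/(TP+FN) and their harmonic mean, the F-score. The recall is
#' mathematically equivalent to the alignment Q-score. The reference is
#' taken as-is and assumed true.
#'
#' When a denominator is zero the corresponding score is undefined and
#' reported as `NA`; the F-score is 0 when precision + recall = 0 and `NA`
#' when either component is undefined.
#'
#' @param inferred,reference [msa] objects over the same sequences (matched
#'   by id; ungapped content must agree).
#' @return an object of class `pair_comparison`: a list with `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f_score`.
#' @export
compare_alignments <- function(inferred, reference) {
  check_comparable(inferred, reference)
  pi <- aligned_pairs(inferred)
  pr <- aligned_pairs(reference)
  tp <- sum(pi %in% pr)
  fp <- length(pi) - tp
  fn <- length(pr) - tp
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f_score <- if (is.na(precision) || is.na(recall)) {
    NA_real_
  } else if (precision + recall == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f_score = f_score),
            class = "pair_comparison")
}

#' @export
print.pair_comparison <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("letter-pair comparison: TP %d, FP %d, FN %d\n",
              x$tp, x$fp, x$fn))
  cat(sprintf("precision %s, recall (Q-score) %s, F-score %s\n",
              fmt(x$precision), fmt(x$recall), fmt(x$f_score)))
  invisible(x)
}

#' Per-column precision of an inferred alignment
#'
#' Each inferred column is treated independently: its precision is the
#' fraction of that column's aligned letter-pairs that also occur in the
#' reference. Columns holding fewer than two residues have no pairs and get
#' `NA` (undefined) rather than a silent zero; such columns are excluded
#' from score-precision binning downstream.
#'
#' @inheritParams compare_alignments
#' @return data.frame with `column` (1-based), `n_pairs` and `precision`.
#' @export
column_precision <- function(inferred, reference) {
  check_comparable(inferred, reference)
  ref <- aligned_pairs(reference)
  cols <- column_pair_sets(inferred)
  n_pairs <- lengths(cols)
  precision <- vapply(cols, function(p) {
    if (length(p) == 0L) NA_real_ else sum(p %in% ref) / length(p)
  }, numeric(1L))
  data.frame(column = seq_along(cols), n_pairs = n_pairs,
             precision = precision)
}
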