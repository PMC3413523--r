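#' Alignment objects
#'
#' An `msa` is an ordered set of identified, equal-length gapped sequences:
#' the universal input/output object of this package. Rows are stored as
#' gapped strings over the residue alphabet plus `"-"`; the ungapped sequence
#' of every row is recoverable by deleting gap characters.
#'
#' @param ids character vector of unique, whitespace-free sequence
#'   identifiers.
#' @param seqs character vector of gapped rows, all the same width. `"."` is
#'   accepted as a gap synonym and converted to `"-"`; residues are
#'   uppercased. The residue alphabet is otherwise not validated: the merge
#'   algorithm is alphabet-agnostic and works for protein and nucleotide
#'   alignments alike.
#' @return An object of class `msa`.
#' @examples
#' msa(c("a", "b"), c("AC-", "A-G"))
#' @export
msa <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(gsub(".", "-", as.character(seqs), fixed = TRUE))
  x <- new_msa(ids, seqs)
  validate_msa(x)
  x
}

# Low-level constructor: no normalization, no validation.
new_msa <- function(ids, seqs) {
  structure(list(ids = ids, seqs = unname(seqs)), class = "msa")
}

validate_msa <- function(x, allow_empty_columns = FALSE) {
  if (length(x$ids) < 1L) {
    msa_abort("alignment must contain at least one record",
              "msamerge_empty_input")
  }
  if (any(!nzchar(x$ids)) || any(grepl("\\s", x$ids))) {
    msa_abort("sequence ids must be non-empty and contain no whitespace",
              "msamerge_bad_id")
  }
  if (anyDuplicated(x$ids)) {
    dup <- unique(x$ids[duplicated(x$ids)])
    msa_abort(sprintf("duplicate sequence id(s): %s",
                      paste(dup, collapse = ", ")),
              "msamerge_duplicate_ids")
  }
  if (length(x$seqs) != length(x$ids)) {
    msa_abort("ids and sequences differ in number", "msamerge_bad_alignment")
  }
  w <- nchar(x$seqs)
  if (length(unique(w)) != 1L) {
    msa_abort("unequal alignment lengths across records",
              "msamerge_unequal_lengths")
  }
  if (w[1L] == 0L && !allow_empty_columns) {
    msa_abort("alignment rows are empty", "msamerge_empty_input")
  }
  invisible(x)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("multiple sequence alignment: %d sequences x %d columns\n",
              length(x$ids), alignment_length(x)))
  show <- utils::head(seq_along(x$ids), 6L)
  for (i in show) {
    s <- x$seqs[i]
    if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
    cat(sprintf("  %-12s %s\n", x$ids[i], s))
  }
  if (length(x$ids) > 6L) cat(sprintf("  ... and %d more\n", length(x$ids) - 6L))
  invisible(x)
}

#' Number of columns in an alignment
#' @param x an [msa] object.
#' @return integer column count.
#' @export
alignment_length <- function(x) {
  stopifnot(inherits(x, "msa"))
  nchar(x$seqs[1L])
}

#' Alignment as a character matrix
#'
#' @param x an [msa] object.
#' @return character matrix, one row per sequence, one column per alignment
#'   column; rownames are the sequence ids.
#' @export
msa_matrix <- function(x) {
  stopifnot(inherits(x, "msa"))
  L <- alignment_length(x)
  m <- matrix("", nrow = length(x$ids), ncol = L,
              dimnames = list(x$ids, NULL))
  if (L > 0L) {
    sp <- strsplit(x$seqs, "", fixed = TRUE)
    for (i in seq_along(sp)) m[i, ] <- sp[[i]]
  }
  m
}

matrix_to_msa <- function(m, ids = rownames(m)) {
  new_msa(ids, apply(m, 1L, paste, collapse = ""))
}

#' Ungapped sequences of an alignment
#' @param x an [msa] object.
#' @return named character vector of sequences with all gaps removed.
#' @export
ungapped_seqs <- function(x) {
  stopifnot(inherits(x, "msa"))
  stats::setNames(gsub("-", "", x$seqs, fixed = TRUE), x$ids)
}

# Remove columns consisting entirely of gaps. Returns list(msa, n_dropped).
drop_allgap_columns <- function(x) {
  m <- msa_matrix(x)
  allgap <- colSums(m != "-") == 0L
  if (!any(allgap)) return(list(msa = x, n_dropped = 0L))
  m <- m[, !allgap, drop = FALSE]
  list(msa = matrix_to_msa(m, x$ids), n_dropped = sum(allgap))
}

#' Read an aligned FASTA file
#'
#' Parses a multi-FASTA file whose records are equal-length gapped rows of
#' one multiple sequence alignment. The id of each record is the first
#' whitespace-delimited token of its header. Residues are uppercased and
#' `"."` gaps converted to `"-"`. Columns consisting entirely of gaps carry
#' no information about residue placement (and would stall the cumulative
#' column encoding), so they are removed with a warning.
#'
#' @param file path to an aligned FASTA file. Ignored when `text` is given.
#' @param text optional character scalar holding FASTA content directly.
#' @return an [msa] object with records in file order.
#' @examples
#' aln <- read_alignment(text = ">a\nAC-\n>b\nA-G\n")
#' alignment_length(aln)
#' @export
read_alignment <- function(file = NULL, text = NULL) {
  if (!is.null(text)) {
    file <- tempfile(fileext = ".fasta")
    on.exit(unlink(file))
    writeLines(text, file)
  }
  if (is.null(file)) usage_abort("read_alignment needs a file or text")
  if (!file.exists(file)) {
    msa_abort(sprintf("no such file: %s", file), "msamerge_missing_file")
  }
  set <- Biostrings::readBStringSet(file)
  if (length(set) == 0L) {
    msa_abort(sprintf("empty FASTA input: %s", file), "msamerge_empty_input")
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(gsub(".", "-", as.character(set), fixed = TRUE))
  x <- new_msa(ids, seqs)
  validate_msa(x)
  dropped <- drop_allgap_columns(x)
  if (dropped$n_dropped > 0L) {
    warning(sprintf("removed %d all-gap column(s) while reading %s",
                    dropped$n_dropped, if (is.null(text)) file else "text"),
            call. = FALSE)
  }
  if (alignment_length(dropped$msa) == 0L) {
    msa_abort("alignment has no non-gap columns", "msamerge_empty_input")
  }
  dropped$msa
}

#' Write an alignment as aligned FASTA
#'
#' Writes `x` in aligned FASTA with sequence lines wrapped at 60 characters.
#' When per-column `scores` are supplied, a tab-separated table with header
#' `column<TAB>score` (1-based column indices) is written alongside.
#'
#' @param x an [msa] object.
#' @param file output FASTA path.
#' @param scores optional numeric vector, one score per alignment column.
#' @param scores_file path for the score table; defaults to
#'   `<file>.scores.tsv` when `scores` is given.
#' @return invisibly, the FASTA path.
#' @export
write_alignment <- function(x, file, scores = NULL, scores_file = NULL) {
  stopifnot(inherits(x, "msa"))
  if (!is.null(scores) && length(scores) != alignment_length(x)) {
    usage_abort(sprintf(
      "scores has length %d but the alignment has %d columns",
      length(scores), alignment_length(x)))
  }
  set <- Biostrings::BStringSet(stats::setNames(x$seqs, x$ids))
  Biostrings::writeXStringSet(set, file, width = 60L)
  if (!is.null(scores)) {
    if (is.null(scores_file)) scores_file <- paste0(file, ".scores.tsv")
    utils::write.table(
      data.frame(column = seq_along(scores), score = scores),
      scores_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' Harmonize alignments of one sequence set
#'
#' Checks that every alignment covers the same sequences (matched by id, not
#' by file position) with byte-identical ungapped content, and reorders the
#' records of each alignment to the record order of the first. Positional
#' matching would silently corrupt a consensus when inputs are sorted
#' differently, hence the id-based contract.
#'
#' @param alignments list of [msa] objects (at least one).
#' @return list of [msa] objects sharing id order and ungapped content.
#' @export
harmonize_alignments <- function(alignments) {
  if (!is.list(alignments) || length(alignments) < 1L ||
      !all(vapply(alignments, inherits, logical(1L), "msa"))) {
    usage_abort("harmonize_alignments needs a non-empty list of msa objects")
  }
  ref_ids <- alignments[[1L]]$ids
  ref_ungapped <- ungapped_seqs(alignments[[1L]])
  out <- vector("list", length(alignments))
  out[[1L]] <- alignments[[1L]]
  for (j in seq_along(alignments)[-1L]) {
    a <- alignments[[j]]
    if (length(a$ids) != length(ref_ids) || !setequal(a$ids, ref_ids)) {
      extra <- setdiff(a$ids, ref_ids)
      missing <- setdiff(ref_ids, a$ids)
      msa_abort(sprintf(
        "alignment %d has a different id set (missing: %s; extra: %s)",
        j,
        if (length(missing)) paste(missing, collapse = ", ") else "none",
        if (length(extra)) paste(extra, collapse = ", ") else "none"),
        "msamerge_id_mismatch")
    }
    ord <- match(ref_ids, a$ids)
    a <- new_msa(ref_ids, a$seqs[ord])
    ug <- ungapped_seqs(a)
    bad <- ref_ids[ug != ref_ungapped]
    if (length(bad) > 0L) {
      msa_abort(sprintf(
        "ungapped sequence differs between alignments for id(s): %s",
        paste(bad, collapse = ", ")),
        "msamerge_sequence_mismatch")
    }
    out[[j]] <- a
  }
  out
}
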