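#' Encode alignment columns as cumulative residue-count tuples
#'
#' Each residue is replaced by its 1-based position within its own ungapped
#' sequence and each gap by the position of the preceding residue, with every
#' sequence assumed to start at 0. A column then becomes an N-tuple of
#' cumulative residue counts (N = number of sequences), which identifies the
#' column's alignment state independently of residue identity: two columns in
#' different alignments of the same sequences are the same column exactly
#' when their tuples are equal.
#'
#' @param aln an [msa] object with no all-gap columns (guaranteed by
#'   [read_alignment]).
#' @return an object of class `msa_indexed`: a list with `keys` (integer
#'   matrix, one row per column), `key_strings` (the comma-joined tuples used
#'   as graph node identifiers), `n_sequences`, `source_key` (the all-zero
#'   tuple) and `sink_key` (the full-length tuple).
#' @examples
#' encode_indices(msa(c("a", "b"), c("AC-", "A-G")))$keys
#' @export
encode_indices <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  m <- msa_matrix(aln)
  cum <- (m != "-") * 1L
  if (ncol(cum) > 1L) cum <- t(apply(cum, 1L, cumsum))
  keys <- t(cum)                       # one row per alignment column
  storage.mode(keys) <- "integer"
  n <- nrow(m)
  # every column must advance at least one sequence (no all-gap columns),
  # and by at most one residue per sequence
  prev <- rbind(rep(0L, n), keys[-nrow(keys), , drop = FALSE])
  step <- keys - prev
  if (any(step < 0L | step > 1L) || any(rowSums(step) < 1L)) {
    msa_abort("alignment contains an all-gap column; sanitize input first",
              "msamerge_bad_alignment")
  }
  structure(list(
    keys = keys,
    key_strings = key_strings(keys),
    n_sequences = n,
    source_key = paste(rep(0L, n), collapse = ","),
    sink_key = paste(keys[nrow(keys), ], collapse = ",")
  ), class = "msa_indexed")
}

key_strings <- function(keys) {
  do.call(paste, c(lapply(seq_len(ncol(keys)), function(j) keys[, j]),
                   list(sep = ",")))
}

parse_keys <- function(strings, n) {
  out <- matrix(0L, nrow = length(strings), ncol = n)
  sp <- strsplit(strings, ",", fixed = TRUE)
  for (i in seq_along(sp)) out[i, ] <- as.integer(sp[[i]])
  out
}

#' Build the column-transition graph of a set of encoded alignments
#'
#' Nodes are column tuples present in at least one constituent alignment;
#' a directed edge joins two tuples that appear as consecutive columns in at
#' least one constituent, and its weight counts the constituents containing
#' that transition. A virtual all-zero source node precedes every
#' constituent's first column, so the first consensus column is scored like
#' any other; the sink is the full-length tuple that every harmonized
#' constituent ends with.
#'
#' @param indexed list of `msa_indexed` objects from [encode_indices], all of
#'   the same (harmonized) sequences.
#' @return an object of class `msa_graph` with nodes, edge list (`edge_from`,
#'   `edge_to`, `edge_w`), per-node incoming-edge index, `source`, `sink` and
#'   `k` (the number of constituents).
#' @export
build_graph <- function(indexed) {
  if (!is.list(indexed) || length(indexed) < 1L ||
      !all(vapply(indexed, inherits, logical(1L), "msa_indexed"))) {
    usage_abort("build_graph needs a non-empty list of msa_indexed objects")
  }
  k <- length(indexed)
  n <- indexed[[1L]]$n_sequences
  if (any(vapply(indexed, `[[`, integer(1L), "n_sequences") != n)) {
    msa_abort("constituents disagree on the number of sequences",
              "msamerge_unharmonized")
  }
  sinks <- vapply(indexed, `[[`, character(1L), "sink_key")
  if (length(unique(sinks)) != 1L) {
    msa_abort("constituents end at different column tuples; harmonize inputs",
              "msamerge_unharmonized")
  }
  source_key <- indexed[[1L]]$source_key

  from <- vector("list", k)
  to <- vector("list", k)
  for (j in seq_len(k)) {
    chain <- c(source_key, indexed[[j]]$key_strings)
    from[[j]] <- chain[-length(chain)]
    to[[j]] <- chain[-1L]
  }
  from <- unlist(from, use.names = FALSE)
  to <- unlist(to, use.names = FALSE)

  ekey <- paste(from, to, sep = ">")
  first <- !duplicated(ekey)
  w <- as.integer(table(ekey)[ekey[first]])
  edge_from <- from[first]
  edge_to <- to[first]

  nodes <- unique(c(source_key, edge_to))
  node_mat <- parse_keys(nodes, n)

  # contract checks: weights in [1, k], edges strictly advance, weight mass
  # equals the total number of constituent columns (source edges included)
  stopifnot(all(w >= 1L), all(w <= k),
            sum(w) == sum(vapply(indexed, function(x) nrow(x$keys),
                                 integer(1L))))
  fi <- match(edge_from, nodes)
  ti <- match(edge_to, nodes)
  sums <- rowSums(node_mat)
  stopifnot(all(sums[ti] > sums[fi]))

  inc <- vector("list", length(nodes))
  sp <- split(seq_along(ti), ti)
  inc[as.integer(names(sp))] <- sp

  structure(list(
    nodes = nodes, node_mat = node_mat, node_sums = sums,
    edge_from = edge_from, edge_to = edge_to, edge_w = w,
    from_idx = fi, to_idx = ti, incoming = inc,
    source = source_key, sink = sinks[1L],
    k = k, n_sequences = n
  ), class = "msa_graph")
}

#' @export
print.msa_graph <- function(x, ...) {
  cat(sprintf(
    "column-transition graph: %d nodes, %d edges, %d constituents, %d sequences\n",
    length(x$nodes), length(x$edge_w), x$k, x$n_sequences))
  invisible(x)
}

# Selection rule shared (conceptually) with the brute-force oracle:
# an incoming edge from u with weight w beats the incumbent from ub with
# weight wb when its score (s(u)+w)/(l(u)+1) is larger. Scores are compared
# by cross-multiplication -- path scores and lengths are integers, so ties
# are exact rather than floating-point accidents. Ties prefer the heavier
# edge, then the lexicographically smallest source tuple.
edge_beats <- function(s_u, l_u, w, key_u, s_ub, l_ub, wb, key_ub) {
  a <- (s_u + w) * (l_ub + 1)
  b <- (s_ub + wb) * (l_u + 1)
  if (a != b) return(a > b)
  if (w != wb) return(w > wb)
  lex_less(key_u, key_ub)
}

#' Select the consensus path through a column-transition graph
#'
#' Runs the per-node dynamic program: nodes are processed in a topological
#' order (ascending tuple sum, ties broken lexicographically); each node's
#' incoming edge e = (x, n) is scored as (s(x) + w(e)) / (l(x) + 1), where
#' s and l are the path score and path length accumulated at x, and the
#' highest-scoring edge is kept as the traceback edge, setting
#' s(n) = s(x) + w(e) and l(n) = l(x) + 1. The consensus path is recovered by
#' following traceback edges from the sink. Note this per-node rule is greedy
#' with respect to the mean edge weight of the full path: it is deterministic
#' and fast but not guaranteed to find the global maximum-mean path.
#'
#' @param graph an `msa_graph` from [build_graph].
#' @return a list with `path_keys` (node tuples from the first column to the
#'   sink; source excluded), `weights` (the traceback edge weights, i.e. raw
#'   column scores), `score` and `length` (path score/length at the sink).
#' @export
solve_graph <- function(graph) {
  stopifnot(inherits(graph, "msa_graph"))
  nodes <- graph$nodes
  nm <- graph$node_mat
  nn <- length(nodes)
  ord <- do.call(order, c(list(graph$node_sums),
                          lapply(seq_len(ncol(nm)), function(j) nm[, j])))
  si <- match(graph$source, nodes)

  s <- numeric(nn)
  l <- numeric(nn)
  parent <- integer(nn)
  pweight <- integer(nn)
  ew <- graph$edge_w
  fi <- graph$from_idx

  for (v in ord) {
    if (v == si) next
    cand <- graph$incoming[[v]]
    if (is.null(cand)) {
      msa_abort("graph node with no incoming edge", "msamerge_internal")
    }
    best <- cand[1L]
    if (length(cand) > 1L) {
      for (e in cand[-1L]) {
        u <- fi[e]
        ub <- fi[best]
        if (edge_beats(s[u], l[u], ew[e], nm[u, ],
                       s[ub], l[ub], ew[best], nm[ub, ])) {
          best <- e
        }
      }
    }
    u <- fi[best]
    s[v] <- s[u] + ew[best]
    l[v] <- l[u] + 1
    parent[v] <- u
    pweight[v] <- ew[best]
  }

  ti <- match(graph$sink, nodes)
  path <- integer(l[ti])
  wts <- integer(l[ti])
  v <- ti
  i <- l[ti]
  while (v != si) {
    path[i] <- v
    wts[i] <- pweight[v]
    v <- parent[v]
    i <- i - 1L
  }
  list(path_keys = nodes[path], weights = wts,
       score = s[ti], length = as.integer(l[ti]))
}

#' Reconstruct the consensus alignment from a graph path
#'
#' For each transition u -> v along the path and each sequence i, the
#' consensus column holds residue number `v[i]` of sequence i when
#' `v[i] = u[i] + 1`, and a gap when `v[i] = u[i]`. Every residue of every
#' sequence is emitted exactly once and in order.
#'
#' @param path_keys character vector of column tuples (source excluded).
#' @param weights integer traceback edge weights, one per column.
#' @param ungapped named character vector of ungapped sequences.
#' @param ids sequence ids in tuple-component order.
#' @param k number of constituent alignments (for score normalization).
#' @return an object of class `msa_consensus`: a list with `alignment` (an
#'   [msa]), `raw_scores` (integer; the number of constituents containing
#'   each column's transition), `normalized_scores` (`raw_scores / k`) and
#'   `k`.
#' @export
decode_consensus <- function(path_keys, weights, ungapped, ids, k) {
  n <- length(ids)
  L <- length(path_keys)
  km <- parse_keys(path_keys, n)
  prev <- rbind(rep(0L, n), km[-L, , drop = FALSE])
  step <- km - prev
  if (any(step < 0L | step > 1L)) {
    msa_abort("path contains a column-tuple jump larger than 1",
              "msamerge_internal")
  }
  seqs <- character(n)
  for (i in seq_len(n)) {
    chars <- strsplit(ungapped[[ids[i]]], "", fixed = TRUE)[[1L]]
    if (km[L, i] != length(chars)) {
      msa_abort("path does not consume every residue", "msamerge_internal")
    }
    row <- rep("-", L)
    row[step[, i] == 1L] <- chars
    seqs[i] <- paste(row, collapse = "")
  }
  structure(list(
    alignment = new_msa(ids, seqs),
    raw_scores = as.integer(weights),
    normalized_scores = as.numeric(weights) / k,
    k = as.integer(k)
  ), class = "msa_consensus")
}

#' @export
print.msa_consensus <- function(x, ...) {
  cat(sprintf(
    "consensus of %d alignment(s): %d sequences x %d columns\n",
    x$k, length(x$alignment$ids), alignment_length(x$alignment)))
  cat(sprintf("column support: mean %.3f, min %.3f, max %.3f\n",
              mean(x$normalized_scores), min(x$normalized_scores),
              max(x$normalized_scores)))
  invisible(x)
}

#' Merge alignments into a scored consensus alignment
#'
#' The full pipeline: harmonize the inputs, encode their columns as
#' cumulative-count tuples, superimpose them into a weighted column-transition
#' graph, select the consensus path by dynamic programming, and reconstruct
#' the consensus alignment. Each consensus column is scored by the number of
#' constituents containing its transition (raw) and by that count divided by
#' the number of constituents (normalized, in (0, 1]).
#'
#' The graph has at most kN + 1 nodes (k constituents, N the longest
#' constituent) and at most k edges in or out of any node, so merging runs in
#' O(N k^2) time: linear in alignment length and independent of the number of
#' sequences.
#'
#' @param alignments list of [msa] objects of the same sequences.
#' @return an `msa_consensus` (see [decode_consensus]) with the extra fields
#'   `n_nodes` and `n_edges` describing the graph.
#' @examples
#' a <- read_alignment(text = ">s1\nA-\n>s2\n-A\n")
#' b <- read_alignment(text = ">s1\nA\n>s2\nA\n")
#' res <- merge_alignments(list(a, b))
#' res$normalized_scores
#' @export
merge_alignments <- function(alignments) {
  alignments <- harmonize_alignments(alignments)
  indexed <- lapply(alignments, encode_indices)
  graph <- build_graph(indexed)
  sol <- solve_graph(graph)
  res <- decode_consensus(sol$path_keys, sol$weights,
                          ungapped_seqs(alignments[[1L]]),
                          alignments[[1L]]$ids, graph$k)
  res$n_nodes <- length(graph$nodes)
  res$n_edges <- length(graph$edge_w)
  res
}
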