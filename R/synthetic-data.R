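# Synthetic alignment worlds for testing: a ground-truth alignment, k
# independently perturbed constituents that agree on most columns but
# disagree on gap placement at a controllable rate, and a brute-force path
# oracle for small graphs.

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Configuration of a synthetic alignment world
#'
#' Fully determines all generated outputs: the same configuration always
#' yields byte-identical alignments. Defaults describe a mid-sized protein
#' family: 8 sequences of 100 residues with 20% gap content, 10 constituent
#' alignments perturbed at rate 0.2.
#'
#' @param n_sequences number of sequences (>= 2).
#' @param length ungapped residue count per sequence (>= 1).
#' @param gap_fraction target per-row gap fraction in \[0, 0.6).
#' @param k number of constituent alignments (>= 1).
#' @param perturb_rate gap-shift moves per alignment column, in \[0, 1\].
#' @param seed integer random seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_sequences = 8L, length = 100L,
                         gap_fraction = 0.2, k = 10L,
                         perturb_rate = 0.2, seed = 1L) {
  cfg <- list(n_sequences = as.integer(n_sequences),
              length = as.integer(length),
              gap_fraction = as.numeric(gap_fraction),
              k = as.integer(k),
              perturb_rate = as.numeric(perturb_rate),
              seed = as.integer(seed))
  if (cfg$n_sequences < 2L) usage_abort("n_sequences must be >= 2")
  if (cfg$length < 1L) usage_abort("length must be >= 1")
  if (cfg$gap_fraction < 0 || cfg$gap_fraction >= 0.6) {
    usage_abort("gap_fraction must lie in [0, 0.6)")
  }
  if (cfg$k < 1L) usage_abort("k must be >= 1")
  if (cfg$perturb_rate < 0 || cfg$perturb_rate > 1) {
    usage_abort("perturb_rate must lie in [0, 1]")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a ground-truth alignment
#'
#' Rows are uniform random amino-acid strings of the configured ungapped
#' length; the alignment is widened so that each row carries approximately
#' `gap_fraction` gaps at uniformly random positions. All-gap columns (rare)
#' are removed. The merge algorithm never inspects residue identity, so a
#' uniform alphabet is adequate; no evolutionary realism (substitution or
#' indel processes) is attempted.
#'
#' @param config a [synth_config].
#' @return an [msa] with ids `seq01`, `seq02`, ...
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n <- config$n_sequences
    len <- config$length
    width <- max(len, as.integer(round(len / (1 - config$gap_fraction))))
    m <- matrix("-", nrow = n, ncol = width)
    for (i in seq_len(n)) {
      pos <- sort(sample.int(width, len))
      m[i, pos] <- sample(AMINO_ACIDS, len, replace = TRUE)
    }
    m <- m[, colSums(m != "-") > 0L, drop = FALSE]
    matrix_to_msa(m, sprintf("seq%02d", seq_len(n)))
  })
}

#' Perturb gap placement in an alignment
#'
#' Applies `ceiling(rate * ncol)` local gap-shift moves: each move swaps a
#' gap with an adjacent residue within one row, which rearranges column
#' membership while preserving every ungapped sequence exactly. Moves whose
#' sampled position admits no legal swap are skipped after a bounded number
#' of attempts. All-gap columns created by the shuffling are removed.
#'
#' @param aln an [msa] object.
#' @param rate moves per alignment column, in \[0, 1\].
#' @param seed integer random seed (deterministic output).
#' @return a perturbed [msa] with identical ungapped content.
#' @export
perturb_alignment <- function(aln, rate, seed) {
  stopifnot(inherits(aln, "msa"))
  if (rate < 0 || rate > 1) usage_abort("rate must lie in [0, 1]")
  m <- msa_matrix(aln)
  n_moves <- ceiling(rate * ncol(m))
  if (n_moves == 0L) return(aln)
  with_seed(seed, {
    n <- nrow(m)
    for (mv in seq_len(n_moves)) {
      for (attempt in 1:20) {
        r <- sample.int(n, 1L)
        gaps <- which(m[r, ] == "-")
        if (length(gaps) == 0L) next
        g <- gaps[sample.int(length(gaps), 1L)]
        dirs <- sample(c(-1L, 1L))
        done <- FALSE
        for (d in dirs) {
          t <- g + d
          if (t >= 1L && t <= ncol(m) && m[r, t] != "-") {
            m[r, g] <- m[r, t]
            m[r, t] <- "-"
            done <- TRUE
            break
          }
        }
        if (done) break
      }
    }
    m <- m[, colSums(m != "-") > 0L, drop = FALSE]
    matrix_to_msa(m, aln$ids)
  })
}

#' Generate constituent alignments from a truth alignment
#'
#' Produces `k` independent perturbations of `truth`, each at the configured
#' `perturb_rate`, with per-constituent seeds derived as `seed + index` for
#' reproducible independence. All outputs harmonize with the truth and with
#' each other.
#'
#' @param truth an [msa], typically from [generate_truth].
#' @param config a [synth_config] (fields `k`, `perturb_rate`, `seed`).
#' @return list of `k` [msa] objects.
#' @export
make_constituents <- function(truth, config) {
  stopifnot(inherits(truth, "msa"), inherits(config, "synth_config"))
  lapply(seq_len(config$k), function(i) {
    perturb_alignment(truth, config$perturb_rate, config$seed + i)
  })
}

#' Brute-force path oracle for small graphs
#'
#' Independent re-derivation of the consensus path for testing: the per-node
#' edge-selection rule is recomputed by naive memoized recursion from the
#' sink (same scoring and tie rules as [solve_graph], independently coded),
#' and the true maximum-mean-weight path is found by exhaustive enumeration
#' of all source-to-sink paths. The two can differ: the per-node rule is
#' greedy with respect to the path mean, and this function exists partly to
#' exhibit such cases.
#'
#' @param graph an `msa_graph` from [build_graph]; must be small enough to
#'   enumerate (at most `max_paths` source-to-sink paths).
#' @param max_paths enumeration guard (default 10000); exceeding it is an
#'   error.
#' @param enumerate run the exhaustive max-mean enumeration (default TRUE);
#'   set FALSE to compute only the memoized-recursion result.
#' @return list with `path_keys` and `weights` (the recursion result,
#'   comparable to [solve_graph]), `max_mean_path_keys`, `max_mean_weights`
#'   and `max_mean` (the exhaustive optimum; NULL when `enumerate` is
#'   FALSE), and `n_paths`.
#' @export
brute_force_path <- function(graph, max_paths = 10000L, enumerate = TRUE) {
  stopifnot(inherits(graph, "msa_graph"))
  nodes <- graph$nodes
  nm <- graph$node_mat
  ew <- graph$edge_w
  fi <- graph$from_idx
  si <- match(graph$source, nodes)
  ti <- match(graph$sink, nodes)

  # --- memoized recursion over the per-node selection rule -----------------
  memo <- vector("list", length(nodes))
  best_state <- function(v) {
    if (v == si) return(list(s = 0, l = 0, parent = NA_integer_, w = NA_integer_))
    if (!is.null(memo[[v]])) return(memo[[v]])
    cand <- graph$incoming[[v]]
    best <- NULL
    for (e in cand) {
      u <- fi[e]
      st <- best_state(u)
      entry <- list(s = st$s + ew[e], l = st$l + 1, parent = u, w = ew[e],
                    ratio_num = st$s + ew[e], ratio_den = st$l + 1)
      if (is.null(best)) {
        best <- entry
      } else {
        a <- entry$ratio_num * best$ratio_den
        b <- best$ratio_num * entry$ratio_den
        take <- if (a != b) a > b
        else if (entry$w != best$w) entry$w > best$w
        else lex_less(nm[entry$parent, ], nm[best$parent, ])
        if (take) best <- entry
      }
    }
    memo[[v]] <<- best
    best
  }
  st <- best_state(ti)
  path <- integer(st$l)
  wts <- integer(st$l)
  v <- ti
  i <- st$l
  while (v != si) {
    stv <- best_state(v)
    path[i] <- v
    wts[i] <- stv$w
    v <- stv$parent
    i <- i - 1L
  }

  if (!enumerate) {
    return(list(path_keys = nodes[path], weights = wts,
                max_mean_path_keys = NULL, max_mean_weights = NULL,
                max_mean = NULL, n_paths = NA_integer_))
  }

  # --- exhaustive max-mean enumeration ------------------------------------
  out_adj <- vector("list", length(nodes))
  sp <- split(seq_along(fi), fi)
  out_adj[as.integer(names(sp))] <- sp
  # deterministic neighbor order: ascending target-tuple (sum, then lex)
  to_idx <- graph$to_idx
  for (u in seq_along(out_adj)) {
    es <- out_adj[[u]]
    if (length(es) > 1L) {
      tgt <- to_idx[es]
      ord <- do.call(order, c(list(graph$node_sums[tgt]),
                              lapply(seq_len(ncol(nm)),
                                     function(j) nm[tgt, j])))
      out_adj[[u]] <- es[ord]
    }
  }
  n_paths <- 0L
  best_mean <- -Inf
  best_path <- integer(0L)
  best_w <- integer(0L)
  walk <- function(v, path_nodes, path_w) {
    if (v == ti) {
      n_paths <<- n_paths + 1L
      if (n_paths > max_paths) {
        msa_abort("path enumeration guard exceeded", "msamerge_too_many_paths")
      }
      mu <- sum(path_w) / length(path_w)
      if (mu > best_mean) {
        best_mean <<- mu
        best_path <<- path_nodes
        best_w <<- path_w
      }
      return(invisible(NULL))
    }
    for (e in out_adj[[v]]) {
      walk(to_idx[e], c(path_nodes, to_idx[e]), c(path_w, ew[e]))
    }
  }
  walk(si, integer(0L), integer(0L))

  list(path_keys = nodes[path], weights = wts,
       max_mean_path_keys = nodes[best_path], max_mean_weights = best_w,
       max_mean = best_mean, n_paths = n_paths)
}
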