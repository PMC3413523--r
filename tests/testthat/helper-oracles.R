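# Shared fixtures and independent oracles. Oracles are written down a
# different implementation path than the package code they check.

# Random gapped alignment via the synthetic generator.
rand_aln <- function(n = 4, len = 20, gap_fraction = 0.25, seed = 1) {
  generate_truth(synth_config(n_sequences = n, length = len,
                              gap_fraction = gap_fraction, seed = seed))
}

# Random small merge instance: truth, constituents and graph.
rand_instance <- function(seed) {
  set.seed(seed)
  cfg <- synth_config(
    n_sequences = sample(2:4, 1),
    length = sample(3:12, 1),
    gap_fraction = stats::runif(1, 0, 0.4),
    k = sample(1:5, 1),
    perturb_rate = stats::runif(1, 0.2, 0.9),
    seed = seed)
  truth <- generate_truth(cfg)
  constituents <- make_constituents(truth, cfg)
  list(cfg = cfg, truth = truth, constituents = constituents,
       graph = build_graph(lapply(constituents, encode_indices)))
}

# Brute-force aligned-pair enumeration by explicit position counters and
# nested loops (no cumulative-count matrices, no combn).
pairs_bruteforce <- function(aln) {
  m <- msa_matrix(aln)
  ids <- aln$ids
  pos <- integer(nrow(m))
  out <- character(0)
  for (j in seq_len(ncol(m))) {
    here <- list()
    for (i in seq_len(nrow(m))) {
      if (m[i, j] != "-") {
        pos[i] <- pos[i] + 1L
        here[[length(here) + 1L]] <- list(id = ids[i], p = pos[i])
      }
    }
    if (length(here) >= 2L) {
      for (a in 1:(length(here) - 1L)) {
        for (b in (a + 1L):length(here)) {
          x <- here[[a]]
          y <- here[[b]]
          if (x$id > y$id) { tmp <- x; x <- y; y <- tmp }
          out <- c(out, paste(x$id, x$p, y$id, y$p, sep = "|"))
        }
      }
    }
  }
  out
}

# Independent Q-score (recall) oracle: per sequence pair, aligned position
# pairs are recovered from shared column indices, not from pair-string sets.
qscore_oracle <- function(inferred, reference) {
  oi <- match(reference$ids, inferred$ids)
  mi <- msa_matrix(inferred)[oi, , drop = FALSE]
  mr <- msa_matrix(reference)
  ci <- lapply(seq_len(nrow(mi)), function(i) which(mi[i, ] != "-"))
  cr <- lapply(seq_len(nrow(mr)), function(i) which(mr[i, ] != "-"))
  n <- nrow(mr)
  total <- 0L
  matched <- 0L
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      shared_r <- intersect(cr[[a]], cr[[b]])
      pr <- paste(match(shared_r, cr[[a]]), match(shared_r, cr[[b]]))
      shared_i <- intersect(ci[[a]], ci[[b]])
      pi_ <- paste(match(shared_i, ci[[a]]), match(shared_i, ci[[b]]))
      total <- total + length(pr)
      matched <- matched + sum(pr %in% pi_)
    }
  }
  if (total == 0L) NA_real_ else matched / total
}
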