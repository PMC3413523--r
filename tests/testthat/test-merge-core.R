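test_that("encode_indices applies the cumulative-count replacement rule", {
  # hand-derived keys for the documented examples
  keys <- encode_indices(msa(c("a", "b"), c("AC-", "A-G")))$keys
  expect_equal(unname(keys), rbind(c(1L, 1L), c(2L, 1L), c(2L, 2L)))

  keys1 <- encode_indices(msa("a", "ABC"))$keys
  expect_equal(unname(keys1), cbind(1:3))

  keys2 <- encode_indices(msa(c("a", "b"), c("A-", "-A")))$keys
  expect_equal(unname(keys2), rbind(c(1L, 0L), c(1L, 1L)))

  idx <- encode_indices(msa(c("a", "b"), c("AC-", "A-G")))
  expect_equal(idx$source_key, "0,0")
  expect_equal(idx$sink_key, "2,2")
})

test_that("build_graph superimposes constituent chains with counted weights", {
  # k identical chains: c edges, each of weight k
  aln <- rand_aln(n = 3, len = 8, gap_fraction = 0.25, seed = 3)
  idx <- encode_indices(aln)
  g <- build_graph(list(idx, idx, idx, idx))
  expect_equal(length(g$edge_w), alignment_length(aln))
  expect_true(all(g$edge_w == 4L))
  # single constituent meets the kN+1 node bound with equality
  g1 <- build_graph(list(idx))
  expect_equal(length(g1$nodes), alignment_length(aln) + 1L)

  # hand-enumerated toy: rows "A-"/"-A" vs "A"/"A"
  x <- encode_indices(msa(c("s1", "s2"), c("A-", "-A")))
  y <- encode_indices(msa(c("s1", "s2"), c("A", "A")))
  g2 <- build_graph(list(x, y))
  expect_setequal(g2$nodes, c("0,0", "1,0", "1,1"))
  edges <- data.frame(from = g2$edge_from, to = g2$edge_to, w = g2$edge_w)
  edges <- edges[order(edges$from, edges$to), ]
  expect_equal(edges$from, c("0,0", "0,0", "1,0"))
  expect_equal(edges$to, c("1,0", "1,1", "1,1"))
  expect_equal(edges$w, c(1L, 1L, 1L))
})

test_that("build_graph rejects unharmonized constituents", {
  a <- encode_indices(msa(c("s1", "s2"), c("AC", "AC")))
  b <- encode_indices(msa(c("s1", "s2"), c("ACG", "AC-")))
  expect_error(build_graph(list(a, b)), class = "msamerge_unharmonized")
})

test_that("solve_graph walks a chain graph and scores it with k", {
  aln <- rand_aln(n = 3, len = 10, gap_fraction = 0.2, seed = 9)
  idx <- encode_indices(aln)
  g <- build_graph(list(idx, idx, idx))
  sol <- solve_graph(g)
  expect_equal(sol$path_keys, idx$key_strings)
  expect_true(all(sol$weights == 3L))
  expect_equal(sol$score, 3 * alignment_length(aln))
  expect_equal(sol$length, alignment_length(aln))
})

test_that("merge is idempotent on k copies and conserves sequences", {
  for (seed in 1:6) {
    aln <- rand_aln(n = 2 + seed %% 4, len = 15, gap_fraction = 0.3,
                    seed = 100 + seed)
    k <- 1 + seed
    res <- merge_alignments(rep(list(aln), k))
    expect_identical(res$alignment$seqs, aln$seqs)
    expect_true(all(res$raw_scores == k))
    expect_true(all(res$normalized_scores == 1))
  }
})

test_that("merge output conserves residues and respects score/size bounds", {
  for (seed in 1:12) {
    inst <- rand_instance(3000 + seed)
    res <- merge_alignments(inst$constituents)
    # residue conservation: deleting gaps reproduces every input sequence
    expect_identical(ungapped_seqs(res$alignment),
                     ungapped_seqs(inst$truth))
    k <- inst$cfg$k
    expect_true(all(res$raw_scores >= 1 & res$raw_scores <= k))
    expect_true(all(res$normalized_scores > 0 & res$normalized_scores <= 1))
    # graph bounds: nodes <= kN + 1, degree <= k
    g <- inst$graph
    N <- max(vapply(inst$constituents, alignment_length, integer(1)))
    expect_lte(length(g$nodes), k * N + 1)
    expect_lte(max(table(g$from_idx)), k)
    expect_lte(max(table(g$to_idx)), k)
    expect_true(all(g$edge_w >= 1 & g$edge_w <= k))
  }
})

test_that("decode_consensus applies the residue/gap emission rule", {
  ug <- c(s1 = "A", s2 = "A")
  # both sequences advance: residue column
  r1 <- decode_consensus("1,1", 2L, ug, c("s1", "s2"), k = 2L)
  expect_equal(r1$alignment$seqs, c("A", "A"))
  # staggered path: gap emitted where the tuple component is unchanged
  r2 <- decode_consensus(c("1,0", "1,1"), c(1L, 1L), ug, c("s1", "s2"), k = 2L)
  expect_equal(r2$alignment$seqs, c("A-", "-A"))
  expect_equal(r2$normalized_scores, c(0.5, 0.5))
})

test_that("toy merge matches exhaustive max-mean enumeration", {
  # two constituents of "A"/"A": staggered and stacked; only 1 residue per
  # sequence, so the consensus is forced to the stacked single column
  x <- read_alignment(text = ">s1\nA-\n>s2\n-A\n")
  y <- read_alignment(text = ">s1\nA\n>s2\nA\n")
  res <- merge_alignments(list(x, y))
  g <- build_graph(lapply(harmonize_alignments(list(x, y)), encode_indices))
  bf <- brute_force_path(g)
  expect_equal(res$alignment$seqs, c("A", "A"))
  expect_equal(res$raw_scores, bf$weights)
  expect_equal(bf$n_paths, 2L)
})

test_that("iterative solve matches the memoized recursive oracle", {
  # acceptance runs the full 200-instance sweep; this is a fast slice
  for (seed in 1:40) {
    inst <- rand_instance(7000 + seed)
    sol <- solve_graph(inst$graph)
    bf <- brute_force_path(inst$graph, enumerate = FALSE)
    expect_identical(sol$path_keys, bf$path_keys)
    expect_identical(sol$weights, bf$weights)
  }
})
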