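test_that("aligned_pairs enumerates r(r-1)/2 pairs per column", {
  expect_setequal(aligned_pairs(msa(c("a", "b"), c("AC", "AC"))),
                  c("a|1|b|1", "a|2|b|2"))
  expect_length(aligned_pairs(msa(c("a", "b"), c("A-", "-A"))), 0)
  expect_length(aligned_pairs(msa(c("a", "b", "c"), c("A", "A", "A"))), 3)
})

test_that("aligned_pairs matches a brute-force nested-loop enumeration", {
  for (seed in 1:8) {
    aln <- rand_aln(n = 2 + seed %% 4, len = 12, gap_fraction = 0.35,
                    seed = 500 + seed)
    expect_setequal(aligned_pairs(aln), pairs_bruteforce(aln))
  }
})

test_that("compare_alignments scores identity and disjoint cases", {
  a <- msa(c("a", "b"), c("ACGT", "ACGT"))
  self <- compare_alignments(a, a)
  expect_equal(self$fp, 0)
  expect_equal(self$fn, 0)
  expect_equal(c(self$precision, self$recall, self$f_score), c(1, 1, 1))

  # shifted alignment: its only pair (a2, b1) is absent from the reference
  x <- msa(c("a", "b"), c("AC-", "-AC"))
  y <- msa(c("a", "b"), c("AC", "AC"))
  d <- compare_alignments(x, y)
  expect_equal(d$tp, 0)
  expect_equal(c(d$precision, d$recall, d$f_score), c(0, 0, 0))
})

test_that("three-sequence toy counts match brute-force set operations", {
  inf <- msa(c("a", "b", "c"), c("AC-G", "A-CG", "ACC-"))
  ref <- msa(c("a", "b", "c"), c("ACG-", "ACG-", "AC-C"))
  got <- compare_alignments(inf, ref)
  pi <- pairs_bruteforce(inf)
  pr <- pairs_bruteforce(ref)
  expect_equal(got$tp, length(intersect(pi, pr)))
  expect_equal(got$fp, length(setdiff(pi, pr)))
  expect_equal(got$fn, length(setdiff(pr, pi)))
  expect_equal(got$precision, got$tp / (got$tp + got$fp))
  expect_equal(got$recall, got$tp / (got$tp + got$fn))
})

test_that("undefined scores are NA, not silent zeros", {
  # single-sequence rows: no pairs anywhere on either side
  a <- msa(c("a", "b"), c("A-", "-A"))
  b <- msa(c("a", "b"), c("-A", "A-"))
  cmp <- compare_alignments(a, b)
  expect_true(is.na(cmp$precision))
  expect_true(is.na(cmp$recall))
  expect_true(is.na(cmp$f_score))
})

test_that("comparison requires harmonizable inputs", {
  a <- msa(c("a", "b"), c("AC", "AC"))
  b <- msa(c("a", "c"), c("AC", "AC"))
  expect_error(compare_alignments(a, b), class = "msamerge_id_mismatch")
  b2 <- msa(c("a", "b"), c("AG", "AC"))
  expect_error(compare_alignments(a, b2),
               class = "msamerge_sequence_mismatch")
})

test_that("count identities hold on random perturbed pairs (property)", {
  for (seed in 1:10) {
    truth <- rand_aln(n = 3 + seed %% 3, len = 25, gap_fraction = 0.3,
                      seed = 800 + seed)
    other <- perturb_alignment(truth, rate = 0.5, seed = 900 + seed)
    ab <- compare_alignments(truth, other)
    ba <- compare_alignments(other, truth)
    # fp/fn swap under argument exchange
    expect_equal(ab$fp, ba$fn)
    expect_equal(ab$fn, ba$fp)
    expect_equal(ab$tp, ba$tp)
    # recall equals the independently coded Q-score
    expect_equal(ab$recall, qscore_oracle(truth, other))
    expect_equal(ba$recall, qscore_oracle(other, truth))
  }
})

test_that("column_precision treats columns independently", {
  a <- msa(c("a", "b"), c("ACG", "ACG"))
  pc <- column_precision(a, a)
  expect_equal(pc$precision, c(1, 1, 1))
  expect_equal(pc$n_pairs, c(1L, 1L, 1L))

  # a column holding a single residue has no pairs: undefined
  x <- msa(c("a", "b"), c("AC-", "A-C"))
  pcx <- column_precision(x, x)
  expect_equal(pcx$n_pairs, c(1L, 0L, 0L))
  expect_true(all(is.na(pcx$precision[2:3])))

  # four-residue inferred column split 2+2 across reference columns:
  # 6 pairs, of which the two within-group pairs survive -> 2/6
  inf <- msa(c("a", "b", "c", "d"), c("A", "A", "A", "A"))
  ref <- msa(c("a", "b", "c", "d"), c("A-", "A-", "-A", "-A"))
  pc4 <- column_precision(inf, ref)
  expect_equal(pc4$n_pairs, 6L)
  expect_equal(pc4$precision, 2 / 6)
})

test_that("column precisions aggregate to the whole-alignment precision", {
  for (seed in 1:6) {
    truth <- rand_aln(n = 4, len = 20, gap_fraction = 0.3, seed = 40 + seed)
    other <- perturb_alignment(truth, rate = 0.4, seed = 50 + seed)
    cmp <- compare_alignments(other, truth)
    pc <- column_precision(other, truth)
    expect_equal(sum(pc$n_pairs), cmp$tp + cmp$fp)
    ok <- !is.na(pc$precision)
    expect_equal(sum(pc$precision[ok] * pc$n_pairs[ok]) / sum(pc$n_pairs[ok]),
                 cmp$precision)
  }
})
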