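test_that("log-odds entries follow the smoothing arithmetic", {
  m <- motif_from_consensus("ACGT", p0 = 1)
  lo <- log_odds(m, pseudocount = 0.01)
  # column (1,0,0,0): smoothed 0.9925-ish against uniform background
  expect_equal(unname(lo[1, "A"]), log2((1 + 0.01 * 0.25) / 1.01 / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(lo[1, "A"]), 1.989, tolerance = 1e-3)
  # uniform motif vs uniform background: all zero
  u <- bns_motif(probs = matrix(0.25, 3, 4))
  expect_true(all(abs(log_odds(u, pseudocount = 0.01)) < 1e-12))
  # doubling one base's background (at fixed normalisation) lowers that
  # base's entry by exactly 1 bit: the log law
  lo1 <- log_odds(m, c(0.2, 0.3, 0.25, 0.25), pseudocount = 0)
  lo2 <- log_odds(m, c(0.4, 0.2, 0.2, 0.2), pseudocount = 0)
  expect_equal(unname(lo2[1, "A"]), unname(lo1[1, "A"]) - 1, tolerance = 1e-12)
  expect_error(log_odds(m, c(0, 0.5, 0.25, 0.25)), "positive")
})

test_that("null distribution is exact: strict consensus and boundary cases", {
  m6 <- motif_from_consensus("ATCGAT", p0 = 1)
  null <- null_score_distribution(log_odds(m6, pseudocount = 0.01))
  expect_equal(sum(null$pmf), 1, tolerance = 1e-9)
  # only one word attains the maximum score
  expect_equal(null$tail[length(null$tail)], 4^-6, tolerance = 1e-12)
  # the minimum score has p-value 1
  expect_equal(bindnseq:::null_pvalue(null, 0L), 1)
})

test_that("DP p-values equal brute-force enumeration for widths <= 6", {
  set.seed(5)
  for (w in c(4L, 5L, 6L)) {
    probs <- matrix(stats::rgamma(4 * w, 1), w, 4)
    probs <- probs / rowSums(probs)
    bg <- c(0.3, 0.2, 0.2, 0.3)
    lo <- log_odds(bns_motif(probs = probs), bg, pseudocount = 0.05)
    null <- null_score_distribution(lo, bg)
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    qs <- apply(words, 1L, function(v) sum(null$qmat[cbind(seq_len(w), v)]))
    wp <- apply(words, 1L, function(v) prod(bg[v]))
    for (s in sort(unique(qs))) {
      expect_equal(bindnseq:::null_pvalue(null, s), sum(wp[qs >= s]),
                   tolerance = 1e-9, info = sprintf("w=%d s=%d", w, s))
    }
  }
})

test_that("probe scans locate the planted motifs at the printed offsets", {
  mz1 <- motif_from_consensus(MIZM1, p0 = 0.97)
  mz2 <- motif_from_consensus(MIZM2, p0 = 0.97)
  hits1 <- scan_sequences(c(P1 = PROBE_P1), mz1, 1e-4)
  expect_equal(nrow(hits1), 1L)
  expect_equal(hits1$start, 5L)
  expect_equal(hits1$strand, "+")
  expect_equal(hits1$matched_sequence, MIZM1)
  # width-6 strict consensus can never reach p < 1e-4 (floor is 4^-6), so
  # the narrow motif is scanned at 1e-3; the palindrome matches both
  # strands at the same offset
  hits2 <- scan_sequences(c(P2 = PROBE_P2), mz2, 1e-3)
  expect_true(all(hits2$start == 9L))
  expect_setequal(hits2$strand, c("+", "-"))
  expect_equal(nrow(scan_sequences(c(CP = PROBE_CP), mz1, 1e-4)), 0L)
  expect_equal(nrow(scan_sequences(c(CP = PROBE_CP), mz2, 1e-3)), 0L)
})

test_that("scans are strand symmetric and tolerate short sequences", {
  m <- motif_from_consensus("ATCGGTAA", p0 = 0.9)
  seqs <- setNames(random_dna(30, 40, seed = 21), paste0("s", 1:30))
  fwd <- scan_sequences(seqs, m, 1e-3)
  mirrored <- scan_sequences(reverse_complement(seqs), m, 1e-3)
  # a match at start on seq maps to start' = len - stop on the revcomp
  key1 <- sort(paste(fwd$seq_id, fwd$start, fwd$strand))
  key2 <- sort(paste(mirrored$seq_id, 40 - mirrored$stop,
                     ifelse(mirrored$strand == "+", "-", "+")))
  expect_equal(key1, key2)
  # sequence shorter than the motif: no matches, no error
  expect_equal(nrow(scan_sequences(c(tiny = "ACGT"), m, 1e-3)), 0L)
})

test_that("fraction_with_match counts sequences once", {
  m <- motif_from_consensus(MIZM2, p0 = 0.97)
  withm <- planted_reads(20, MIZM2, len = 21, seed = 31)
  expect_equal(fraction_with_match(withm, m, 1e-3), 1.0)
  none <- rep(strrep("G", 21), 10)
  expect_equal(fraction_with_match(none, m, 1e-3), 0.0)
  expect_error(fraction_with_match(character(0), m), "empty")
})

test_that("compare_motifs: self-comparison and reverse-complement symmetry", {
  q <- motif_from_consensus(MIZM1, p0 = 0.85)
  self <- compare_motifs(q, q, n_permutations = 200, seed = 4)
  expect_equal(self$offset, 0L)
  expect_equal(self$orientation, "forward")
  expect_equal(self$score, 1, tolerance = 1e-12)
  rc <- compare_motifs(q, reverse_complement(q), n_permutations = 200, seed = 4)
  expect_equal(rc$orientation, "reverse_complement")
  expect_equal(rc$score, 1, tolerance = 1e-12)
  expect_true(all(rc$e_value >= rc$p_value))
})

test_that("the hexamer motif aligns to the decamer's first six columns", {
  mz1 <- motif_from_consensus(MIZM1, p0 = 0.85)
  mz2 <- motif_from_consensus(MIZM2, p0 = 0.85)
  res <- compare_motifs(mz2, mz1, n_permutations = 1000, seed = 8)
  expect_equal(res$offset, 0L)
  # 5 of 6 consensus characters identical over the aligned window
  aligned <- substr(MIZM1, 1, 6)
  expect_equal(6L - hamming(MIZM2, aligned), 5L)
  # six near-one-hot columns from a near-palindromic base multiset retain
  # alignable shuffles, so significance under the column-shuffle null is
  # genuinely modest; assert the ordering rather than a tight cutoff
  expect_lt(res$p_value, 0.25)
  expect_gte(res$e_value, res$p_value)
})

test_that("comparison p-values are super-uniform under a shuffled null", {
  set.seed(12)
  q <- motif_from_consensus("ATCGGTAATC", p0 = 0.8)
  targets <- lapply(1:40, function(i) {
    probs <- matrix(stats::rgamma(40, 1), 10, 4)
    bns_motif(probs = probs / rowSums(probs), id = paste0("t", i))
  })
  res <- compare_motifs(q, targets, n_permutations = 200, seed = 13)
  # P(p <= a) <= a up to Monte Carlo noise: check at a = 0.1
  expect_lt(mean(res$p_value <= 0.1), 0.25)
  expect_error(compare_motifs(motif_from_consensus("ACG", p0 = 0.9), targets),
               "width")
})
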