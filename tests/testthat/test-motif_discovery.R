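test_that("seed motifs follow the p0 rule and cap at available records", {
  records <- data.frame(kmer = c("ATCGAT", "GGGGGG"),
                        observed_count = c(50L, 20L),
                        observed_freq = c(0.1, 0.04),
                        expected_freq = c(0.01, 0.01),
                        fold_enrichment = c(10, 4))
  seeds <- seed_motifs(records, n_seeds = 5, p0 = 0.7)
  expect_length(seeds, 2L)
  expect_equal(unname(seeds[[1]]$probs[1, ]), c(0.7, 0.1, 0.1, 0.1))
  expect_equal(consensus(seeds[[1]]), "ATCGAT")
  expect_equal(seeds[[1]]$enrichment_score, 10)
  expect_error(seed_motifs(records[0, ]), "empty")
})

test_that("ZOOPS EM recovers a planted site and keeps the likelihood monotone", {
  reads <- planted_reads(500, "ATCGAT", len = 21, seed = 51)
  fit <- em_zoops(reads, motif_from_consensus("ATCGAT", p0 = 0.7))
  expect_equal(consensus(fit$motif), "ATCGAT")
  expect_gte(fit$gamma, 0.95)
  expect_true(all(diff(fit$log_likelihood) >= -1e-8))
})

test_that("ZOOPS EM on pure background yields only a diffuse fit", {
  # an unregularised ZOOPS EM on noise drifts to a diffuse low-information
  # motif whose gamma is ill-determined (it can absorb background mass), so
  # the discriminating signature of a null fit is the information content,
  # far below the planted-signal regime (~2 bits per column, gamma >= 0.95)
  reads <- simulate_background(500, 21, seed = 52)
  fit <- em_zoops(reads, motif_from_consensus("ATCGAT", p0 = 0.7))
  ic <- sum(fit$motif$probs * log2(pmax(fit$motif$probs, 1e-12) / 0.25))
  expect_lt(ic, 4)
  expect_lt(fit$gamma, 0.8)
  expect_true(all(diff(fit$log_likelihood) >= -1e-8))
})

test_that("a background-equal initial motif yields uniform first posteriors", {
  # with PWM = background the likelihood ratio is 1 at every offset, so the
  # first E-step's site posterior mass is flat; one M-step then leaves the
  # motif at background and gamma at its prior
  reads <- simulate_background(200, 21, seed = 53)
  init <- bns_motif(probs = matrix(0.25, 6, 4))
  fit <- em_zoops(reads, init, gamma0 = 0.5, max_iter = 1)
  expect_true(max(abs(fit$motif$probs - 0.25)) < 0.01)
  expect_equal(fit$gamma, 0.5, tolerance = 1e-6)
})

test_that("em_zoops rejects sequences shorter than the motif", {
  expect_error(em_zoops(c("ACGT"), motif_from_consensus("ATCGAT", p0 = 0.7)),
               "at least as long")
})

test_that("match-back keeps consensus reads and obeys the score fraction", {
  m <- motif_from_consensus(MIZM1, p0 = 0.97)
  withm <- planted_reads(50, MIZM1, len = 21, seed = 61)
  expect_equal(match_back(withm, m, score_fraction = 1), withm)
  # lowering the fraction only relaxes the threshold: retained sets nest,
  # and the frac -> 0 limit is "any positive-scoring window"
  bg <- c(withm, simulate_background(200, 21, seed = 62))
  k1 <- match_back(bg, m, score_fraction = 0.9)
  k2 <- match_back(bg, m, score_fraction = 0.5)
  k3 <- match_back(bg, m, score_fraction = 1e-6)
  expect_true(all(k1 %in% k2))
  expect_true(all(k2 %in% k3))
  expect_true(all(withm %in% k1))
  expect_error(match_back(bg, m, score_fraction = 0), "score_fraction")
})

test_that("match-back retention on background matches the null tail rate", {
  m <- motif_from_consensus(MIZM1, p0 = 0.85)
  lodds <- log_odds(m, rep(0.25, 4), 0.01)
  null <- null_score_distribution(lodds)
  thr <- 0.9 * bindnseq:::max_score(lodds)
  # per-window per-strand tail probability at the threshold score
  tail_p <- bindnseq:::null_pvalue(null, ceiling((thr - null$offset) / null$step))
  n <- 2e4
  bg <- simulate_background(n, 21, seed = 63)
  kept <- length(match_back(bg, m, score_fraction = 0.9))
  # expected reads with >= 1 matching window among 12 offsets x 2 strands
  expected <- n * (1 - (1 - tail_p)^24)
  expect_lt(abs(kept - expected), 4 * sqrt(expected) + 2)
})

test_that("discovery recovers a planted motif from a small library", {
  conds <- data.frame(barcode = "AGG", protein_nM = 50, salt_mM = 50)
  # strong cheap selection so the scaled-down library carries enough sites
  strong <- selection_model(alpha = 0, epsilon = 0.005, lambda = 0.3)
  sim <- simulate_bns_library(conds, strong, n_selected = 15000,
                              n_background = 100, seed = 71)
  mots <- discover_motifs(sim$reads$AGG$region, widths = 10L,
                          cluster_size = 5000, n_rounds = 2, n_seeds = 2,
                          seed = 72)
  expect_true(length(mots) >= 1L)
  expect_true(consensus(mots[[1]]) %in% c(MIZM1, reverse_complement(MIZM1)))
  expect_gt(mots[[1]]$enrichment_score, 5)
})

test_that("discovery is deterministic given the seed", {
  reads <- c(planted_reads(400, MIZM2, len = 21, seed = 81),
             simulate_background(1600, 21, seed = 82))
  m1 <- discover_motifs(reads, widths = 6L, cluster_size = 1000,
                        n_rounds = 1, n_seeds = 2, seed = 5)
  m2 <- discover_motifs(reads, widths = 6L, cluster_size = 1000,
                        n_rounds = 1, n_seeds = 2, seed = 5)
  expect_equal(lapply(m1, `[[`, "probs"), lapply(m2, `[[`, "probs"))
  expect_equal(consensus(m1[[1]]), MIZM2)
})

test_that("discovery on the reverse-complemented pool gives the same canon", {
  reads <- c(planted_reads(400, MIZM1, len = 21, seed = 83),
             simulate_background(1600, 21, seed = 84))
  fwd <- discover_motifs(reads, widths = 10L, cluster_size = 1000,
                         n_rounds = 1, n_seeds = 2, seed = 6)
  rev <- discover_motifs(reverse_complement(reads), widths = 10L,
                         cluster_size = 1000, n_rounds = 1, n_seeds = 2,
                         seed = 6)
  canon <- function(ms) sort(vapply(ms, function(m) {
    cc <- consensus(m); min(cc, reverse_complement(cc))
  }, ""))
  expect_equal(canon(fwd), canon(rev))
})

test_that("pure background discovery reports no strong enrichment", {
  reads <- simulate_background(5e4, 21, seed = 85)
  mots <- discover_motifs(reads, widths = 6L, cluster_size = 3000,
                          n_rounds = 1, n_seeds = 3, seed = 7)
  scores <- vapply(mots, `[[`, 0, "enrichment_score")
  expect_true(all(scores < 2))
})
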