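toy_genes <- function() {
  genes <- data.frame(
    gene_id = c("gplus", "gminus"),
    chrom = "chr1",
    strand = c("+", "-"),
    tx_start = c(10000L, 1000L),
    tx_end = c(14000L, 5000L)
  )
  genes$exon_starts <- list(c(10000L, 12000L), c(1000L, 3000L))
  genes$exon_ends <- list(c(11000L, 14000L), c(2000L, 5000L))
  genes
}

peaks_at <- function(mids, width = 200L) {
  data.frame(chrom = "chr1", start = mids - width %/% 2L,
             end = mids + width %/% 2L,
             peak_id = sprintf("p%d", seq_along(mids)))
}

test_that("peak sequences are exact genome slices", {
  genome <- c(chr1 = "ACGTACGTACGTACGTACGT")
  peaks <- data.frame(chrom = "chr1", start = c(0L, 4L), end = c(5L, 12L),
                      peak_id = c("a", "b"))
  seqs <- peak_sequences(peaks, genome)
  expect_equal(unname(seqs), c("ACGTA", "ACGTACGT"))
  expect_error(peak_sequences(data.frame(chrom = "chrX", start = 0L, end = 2L,
                                         peak_id = "x"), genome), "chrX")
  expect_error(peak_sequences(data.frame(chrom = "chr1", start = 10L,
                                         end = 30L, peak_id = "y"), genome),
               "past the end")
})

test_that("TSS distances follow the strand-adjusted sign convention", {
  genes <- toy_genes()
  # + strand TSS at 10000: midpoint 8000 is 2 kb upstream
  ann <- annotate_peaks(peaks_at(c(10000L, 8000L, 6000L)), genes)
  expect_equal(ann$nearest_gene, c("gplus", "gplus", "gminus"))
  expect_equal(ann$tss_distance[1], 0)
  expect_equal(ann$tss_distance[2], -2000)
  # - strand gene, TSS at 4999 (tx_end 5000): midpoint 6000 lies upstream
  expect_equal(ann$tss_distance[3], -1001)
  expect_equal(ann$region_class[1], "promoter")
})

test_that("nearest TSS agrees with a brute-force search on random input", {
  g <- simulate_genome_peaks(seed = 31, n_genes = 12, n_peaks = 50,
                             proximal_bias = 0.7)
  ann <- annotate_peaks(g$peaks, g$genes, g$truth$has_motif)
  expect_equal(ann$tss_distance, g$truth$true_tss_distance)
  # brute force re-computation
  tssv <- tss_position(g$genes)
  mids <- (g$peaks$start + g$peaks$end) %/% 2L
  brute <- vapply(mids, function(mid) {
    d <- abs(mid - tssv)
    i <- order(d, pmin(g$genes$tx_start, g$genes$tx_end), g$genes$gene_id)[1]
    if (g$genes$strand[i] == "+") mid - tssv[i] else tssv[i] - mid
  }, numeric(1))
  expect_equal(ann$tss_distance, brute)
})

test_that("region classes partition the peaks with documented priority", {
  genes <- toy_genes()
  mids <- c(10000L,  # promoter (at + TSS)
            9200L,   # promoter (-1 kb .. +100 window)
            13950L,  # tts window of gplus
            10500L,  # inside exon 1 of gplus
            11500L,  # intron of gplus
            40000L)  # intergenic
  ann <- annotate_peaks(peaks_at(mids), genes)
  expect_equal(ann$region_class,
               c("promoter", "promoter", "tts", "exon", "intron", "intergenic"))
  expect_true(all(ann$region_class %in%
                    c("promoter", "tts", "exon", "intron", "intergenic")))
  # promoter class implies the documented distance window
  prom <- ann$region_class == "promoter"
  expect_true(all(ann$tss_distance[prom] >= -1000 & ann$tss_distance[prom] <= 100))
  expect_error(annotate_peaks(peaks_at(100L), genes[0, ]), "empty")
})

test_that("proximal fraction and clamped histogram behave as documented", {
  ann <- data.frame(peak_id = paste0("p", 1:4), chrom = "chr1",
                    midpoint = 0L, nearest_gene = "g",
                    tss_distance = c(-1200, 300, 1500, 120000),
                    region_class = "intergenic", has_motif = FALSE)
  expect_equal(proximal_fraction(ann), 3 / 4)
  expect_equal(proximal_fraction(ann, window_bp = 100), 0)
  expect_error(proximal_fraction(ann[0, ]), "empty")
  h <- density_summary(ann, clamp_bp = 50000, bin_width = 1000)
  expect_equal(sum(h$count), 4L)
  # the +120 kb peak is clamped into the topmost (+50 kb boundary) bin
  expect_equal(h$count[length(h$count)], 1L)
  expect_equal(h$bin_end[length(h$count)], 50000)
  sym <- ann; sym$tss_distance <- c(-2500, 2500, -500, 500)
  hs <- density_summary(sym, 50000, 1000)
  expect_equal(hs$count, rev(hs$count))
  expect_error(density_summary(ann, bin_width = 0), "bin_width")
})

test_that("chi-squared matches the closed form and its symmetries", {
  mk_ann <- function(tab) {
    # tab rows: motif FALSE/TRUE; cols: proximal FALSE/TRUE
    data.frame(
      peak_id = paste0("p", seq_len(sum(tab))), chrom = "chr1", midpoint = 0L,
      nearest_gene = "g",
      tss_distance = rep(c(1e6, 0, 1e6, 0), tab[c(1, 3, 2, 4)]),
      region_class = "intergenic",
      has_motif = rep(c(FALSE, FALSE, TRUE, TRUE), tab[c(1, 3, 2, 4)])
    )
  }
  # table rows (10, 90) and (60, 40): hand-computed chi2 = 54.945
  ann <- mk_ann(matrix(c(10, 60, 90, 40), 2))
  res <- contingency_chi2(ann)
  expect_equal(res$chi2, 54.945, tolerance = 1e-3)
  expect_lt(res$p_value, 1e-12)
  # proportional rows: independence, chi2 = 0
  res0 <- contingency_chi2(mk_ann(matrix(c(20, 10, 80, 40), 2)))
  expect_equal(res0$chi2, 0, tolerance = 1e-12)
  # swapping rows leaves the statistic unchanged
  resw <- contingency_chi2(mk_ann(matrix(c(60, 10, 40, 90), 2)))
  expect_equal(resw$chi2, res$chi2, tolerance = 1e-12)
  expect_equal(resw$p_value, res$p_value, tolerance = 1e-12)
  # degenerate margin flags instead of erroring
  deg <- mk_ann(matrix(c(50, 0, 50, 0), 2))
  resd <- contingency_chi2(deg)
  expect_true(resd$degenerate)
  expect_equal(resd$chi2, 0)
})

test_that("synthetic truth tables recover the configured proximal bias", {
  g <- simulate_genome_peaks(seed = 41, n_genes = 40, n_peaks = 400,
                             frac_motif_peaks = 0.5, proximal_bias = 0.85)
  ann <- annotate_peaks(g$peaks, g$genes, g$truth$has_motif)
  pf_free <- proximal_fraction(ann[!ann$has_motif, ])
  pf_with <- proximal_fraction(ann[ann$has_motif, ])
  se <- sqrt(0.85 * 0.15 / 200)
  expect_lt(abs(pf_free - 0.85), 4 * se)
  expect_lt(abs(pf_with - 0.15), 4 * se)
  res <- contingency_chi2(ann)
  expect_lt(res$p_value, 1e-4)
})
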