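# Peak-position analyses: peak sequences from a genome, signed
# strand-adjusted distance to the nearest transcription start site,
# proximal fractions, gene-centred region classification
# (promoter/TTS/exon/intron/intergenic), clamped distance histograms, and
# 2x2 chi-squared tests of motif presence versus TSS proximity.

#' Extract peak sequences from a genome
#'
#' Forward-strand sequence of each half-open `[start, end)` interval.
#'
#' @param peaks data frame from [read_bed()].
#' @param genome named character vector of contig sequences (e.g. from
#'   [read_fasta()]).
#' @return a named character vector, one sequence per peak, named by
#'   `peak_id`.
#' @export
peak_sequences <- function(peaks, genome) {
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing)) {
    stop(sprintf("chromosomes absent from genome: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  over <- peaks$end > nchar(genome[peaks$chrom])
  if (any(over)) {
    stop(sprintf("peak %s extends past the end of %s",
                 peaks$peak_id[which(over)[1L]],
                 peaks$chrom[which(over)[1L]]), call. = FALSE)
  }
  out <- substr(genome[peaks$chrom], peaks$start + 1L, peaks$end)
  stats::setNames(unname(out), peaks$peak_id)
}

#' Annotate peaks by distance to the nearest TSS and genomic region class
#'
#' Distance is measured from the peak midpoint, `floor((start + end) / 2)`,
#' to the nearest TSS by absolute distance (ties broken by lower gene
#' coordinate, then gene id), and is reported strand-adjusted: negative
#' means the peak lies upstream of that gene's TSS. The region class is
#' evaluated at the midpoint against the nearest gene's model, with
#' priority promoter > tts > exon > intron > intergenic, where the
#' promoter is the window -1 kb to +100 bp around the TSS and the TTS
#' region is -100 bp to +1 kb around the transcription termination site,
#' both in strand-adjusted coordinates.
#'
#' @param peaks data frame from [read_bed()].
#' @param genes gene table from [read_gene_table()].
#' @param motif_flags optional logical vector (or vector of peak ids with a
#'   motif) setting the `has_motif` column.
#' @return a data frame with columns `peak_id`, `chrom`, `midpoint`,
#'   `nearest_gene`, `tss_distance`, `region_class`, `has_motif`.
#' @export
annotate_peaks <- function(peaks, genes, motif_flags = NULL) {
  if (nrow(genes) == 0L) stop("gene list is empty", call. = FALSE)
  mid <- (peaks$start + peaks$end) %/% 2L
  tss <- tss_position(genes)
  tts <- tts_position(genes)
  low_coord <- pmin(genes$tx_start, genes$tx_end)
  n <- nrow(peaks)
  nearest <- integer(n)
  for (i in seq_len(n)) {
    same <- which(genes$chrom == peaks$chrom[i])
    cand <- if (length(same)) same else seq_len(nrow(genes))
    d <- abs(mid[i] - tss[cand])
    nearest[i] <- cand[order(d, low_coord[cand], genes$gene_id[cand])[1L]]
  }
  g_strand <- genes$strand[nearest]
  sign_adj <- ifelse(g_strand == "+", 1L, -1L)
  tss_distance <- sign_adj * (mid - tss[nearest])
  tts_distance <- sign_adj * (mid - tts[nearest])
  in_exon <- vapply(seq_len(n), function(i) {
    gi <- nearest[i]
    any(mid[i] >= genes$exon_starts[[gi]] & mid[i] < genes$exon_ends[[gi]])
  }, logical(1))
  in_tx <- mid >= genes$tx_start[nearest] & mid < genes$tx_end[nearest] &
    peaks$chrom == genes$chrom[nearest]
  region_class <- ifelse(
    tss_distance >= -1000 & tss_distance <= 100, "promoter",
    ifelse(tts_distance >= -100 & tts_distance <= 1000, "tts",
           ifelse(in_tx & in_exon, "exon",
                  ifelse(in_tx, "intron", "intergenic"))))
  has_motif <- if (is.null(motif_flags)) {
    rep(NA, n)
  } else if (is.logical(motif_flags)) {
    stopifnot(length(motif_flags) == n)
    motif_flags
  } else {
    peaks$peak_id %in% motif_flags
  }
  data.frame(peak_id = peaks$peak_id, chrom = peaks$chrom, midpoint = mid,
             nearest_gene = genes$gene_id[nearest],
             tss_distance = as.numeric(tss_distance),
             region_class = region_class, has_motif = has_motif)
}

#' Fraction of peaks proximal to a TSS
#'
#' @param annotations data frame from [annotate_peaks()].
#' @param window_bp absolute-distance window defining "proximal"
#'   (default 1,500 bp).
#' @return a proportion in `[0, 1]`.
#' @export
proximal_fraction <- function(annotations, window_bp = 1500) {
  if (nrow(annotations) == 0L) stop("empty annotation set", call. = FALSE)
  stopifnot(window_bp > 0)
  mean(abs(annotations$tss_distance) <= window_bp)
}

#' Histogram of TSS distances, clamped at a maximum distance
#'
#' Distances beyond `clamp_bp` are tallied at +/- `clamp_bp` (the
#' convention used for peak-position density plots), then binned.
#'
#' @param annotations data frame from [annotate_peaks()].
#' @param clamp_bp clamping distance (default 50,000 bp).
#' @param bin_width histogram bin width in bp.
#' @return a data frame with columns `bin_start`, `bin_end`, `count`; the
#'   counts sum to `nrow(annotations)`.
#' @export
density_summary <- function(annotations, clamp_bp = 50000, bin_width = 1000) {
  stopifnot(clamp_bp > 0)
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  d <- pmin(pmax(annotations$tss_distance, -clamp_bp), clamp_bp)
  breaks <- seq(-clamp_bp, clamp_bp, by = bin_width)
  if (breaks[length(breaks)] < clamp_bp) breaks <- c(breaks, clamp_bp)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  data.frame(bin_start = breaks[-length(breaks)],
             bin_end = breaks[-1L],
             count = counts)
}

#' Chi-squared test of motif presence versus TSS proximity
#'
#' Builds the 2x2 table of (has motif x proximal within `window_bp`) and
#' applies Pearson's chi-squared test without continuity correction
#' (df = 1). Degenerate tables (an empty margin) return `chi2 = 0` with a
#' `degenerate` flag and `p_value = NA`.
#'
#' @param annotations data frame from [annotate_peaks()] with a non-NA
#'   `has_motif` column.
#' @param window_bp proximity window in bp.
#' @return a list of class `contingency_result`: `table` (2x2 counts),
#'   `chi2`, `df`, `p_value`, `degenerate`.
#' @export
contingency_chi2 <- function(annotations, window_bp = 1500) {
  if (nrow(annotations) == 0L) stop("empty annotation set", call. = FALSE)
  if (anyNA(annotations$has_motif)) {
    stop("annotations need a has_motif flag", call. = FALSE)
  }
  proximal <- abs(annotations$tss_distance) <= window_bp
  tab <- table(factor(annotations$has_motif, levels = c(FALSE, TRUE)),
               factor(proximal, levels = c(FALSE, TRUE)),
               dnn = c("has_motif", "proximal"))
  degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  if (degenerate) {
    res <- list(table = tab, chi2 = 0, df = 1L, p_value = NA_real_,
                degenerate = TRUE)
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    res <- list(table = tab, chi2 = unname(ct$statistic), df = 1L,
                p_value = unname(ct$p.value), degenerate = FALSE)
  }
  structure(res, class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  if (x$degenerate) {
    cat("degenerate table: chi-squared not computed\n")
  } else {
    cat(sprintf("chi2 = %.3f, df = 1, p = %.3g\n", x$chi2, x$p_value))
  }
  invisible(x)
}
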