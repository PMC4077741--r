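# End-to-end orchestration: selection-library analysis (demultiplex ->
# enrich -> discover -> classify hits) and the peak reanalysis (extract ->
# scan -> annotate -> test). Every intermediate artifact is a documented
# format re-readable by the seqio readers.

# align a consensus against a canonical consensus: minimum mismatches over
# all full-overlap ungapped placements of the shorter in the longer, both
# orientations
consensus_distance <- function(cons, canonical) {
  a <- cons; b <- canonical
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  best <- nchar(a)
  for (cand in c(a, reverse_complement(a))) {
    for (off in 0:(nchar(b) - nchar(cand))) {
      d <- hamming(cand, substr(b, off + 1L, off + nchar(cand)))
      if (d < best) best <- d
    }
  }
  best
}

classify_hits <- function(motifs, canonical) {
  if (!length(motifs)) {
    return(stats::setNames(integer(length(canonical) + 1L), c(canonical, "other")))
  }
  lab <- vapply(motifs, function(m) {
    d <- vapply(canonical, function(cc) consensus_distance(consensus(m), cc), 0)
    if (min(d) <= 1) canonical[which.min(d)] else "other"
  }, "")
  tab <- table(factor(lab, levels = c(canonical, "other")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Run the full Bind-n-Seq analysis pipeline
#'
#' Demultiplexes a barcoded read pool into conditions, computes per-
#' condition k-mer fold enrichment, elicits the top motifs per condition
#' with [discover_motifs()], and tallies the discovered hits by nearest
#' canonical consensus (within one mismatch over the best ungapped
#' alignment, both orientations). Input is either a FASTQ path or a read
#' data frame; deterministic given `seed`.
#'
#' @param reads path to a barcoded FASTQ file, or a read data frame from
#'   [read_fastq()] / [simulate_bns_library()].
#' @param conditions condition table (see [bns_conditions()]); only
#'   conditions present in it are analysed.
#' @param canonical character vector of canonical consensus sequences used
#'   to classify hits.
#' @param enrichment_k k-mer length for the per-condition enrichment table.
#' @param min_mean_q demultiplexing quality threshold.
#' @param seed integer seed (fans out to per-condition discovery seeds).
#' @param out_dir optional directory; per-condition motifs are written in
#'   MEME minimal format and enrichment tables as TSV.
#' @param ... further arguments passed to [discover_motifs()].
#' @return a list of class `bns_report`: `per_condition` (each with
#'   `enrichment`, `motifs`, `tally`), `tally` (summed across conditions),
#'   `conditions`.
#' @export
run_bns_pipeline <- function(reads, conditions,
                             canonical = c("ATCGGTAATC", "ATCGAT"),
                             enrichment_k = 10L, min_mean_q = 0,
                             seed = 1L, out_dir = NULL, ...) {
  if (is.character(reads) && length(reads) == 1L) {
    if (!file.exists(reads)) {
      stop(sprintf("FASTQ file not found: %s", reads), call. = FALSE)
    }
    reads <- read_fastq(reads)
  }
  dm <- demultiplex(reads, conditions, min_mean_q)
  empty <- names(dm$assigned)[vapply(dm$assigned, nrow, 0L) == 0L]
  if (length(empty)) {
    stop(sprintf("no reads after demultiplexing for barcode(s): %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_condition <- vector("list", nrow(conditions))
  names(per_condition) <- conditions$barcode
  for (ci in seq_len(nrow(conditions))) {
    bc <- conditions$barcode[ci]
    regions <- dm$assigned[[bc]]$region
    message(sprintf("[bns] condition %s: %d reads", bc, length(regions)))
    enr <- fold_enrichment(count_kmers(regions, enrichment_k, "both"))
    motifs <- discover_motifs(regions, seed = seed + ci, ...)
    tally <- classify_hits(motifs, canonical)
    per_condition[[bc]] <- list(enrichment = enr, motifs = motifs,
                                tally = tally)
    if (!is.null(out_dir)) {
      utils::write.table(utils::head(enr, 100L),
                         file.path(out_dir, sprintf("enrichment_%s.tsv", bc)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (length(motifs)) {
        write_meme(motifs, file.path(out_dir, sprintf("motifs_%s.txt", bc)))
      }
    }
  }
  tally <- Reduce(`+`, lapply(per_condition, `[[`, "tally"))
  structure(list(per_condition = per_condition, tally = tally,
                 conditions = conditions),
            class = "bns_report")
}

#' Run the ChIP-seq peak reanalysis
#'
#' Extracts peak sequences from the genome, flags peaks containing a motif
#' instance (exact scan p-value below `p_threshold`), annotates every peak
#' with its signed distance to the nearest TSS and region class, and
#' summarises: motif occurrence fraction, proximal fractions split by
#' motif flag, a clamped distance histogram per flag, per-class counts,
#' and the 2x2 chi-squared test of motif presence versus proximity.
#'
#' @param peaks BED path or peak data frame from [read_bed()].
#' @param genome FASTA path or named character vector.
#' @param genes gene-table path or data frame from [read_gene_table()].
#' @param motif a [bns_motif], a MEME file path (first motif is used), or a
#'   consensus string.
#' @param p_threshold scan p-value cutoff (default 1e-4).
#' @param window_bp proximity window (default 1,500 bp).
#' @param clamp_bp,bin_width histogram parameters.
#' @param out_dir optional directory for TSV outputs.
#' @return a list of class `peak_report`: `annotations`, `motif_fraction`,
#'   `proximal_fraction` (named: with/without motif), `histogram` (list by
#'   flag), `region_counts`, `contingency`.
#' @export
run_peak_reanalysis <- function(peaks, genome, genes, motif,
                                p_threshold = 1e-4, window_bp = 1500,
                                clamp_bp = 50000, bin_width = 1000,
                                out_dir = NULL) {
  if (is.character(peaks) && length(peaks) == 1L) peaks <- read_bed(peaks)
  if (nrow(peaks) == 0L) stop("empty peak set", call. = FALSE)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (is.character(genes) && length(genes) == 1L) genes <- read_gene_table(genes)
  if (is.character(motif)) {
    motif <- if (file.exists(motif)) read_meme(motif)[[1L]] else
      motif_from_consensus(motif, p0 = 1)
  }
  seqs <- peak_sequences(peaks, genome)
  hits <- scan_sequences(seqs, motif, p_threshold)
  flags <- peaks$peak_id %in% hits$seq_id
  message(sprintf("[peaks] %d/%d peaks contain the motif", sum(flags),
                  nrow(peaks)))
  ann <- annotate_peaks(peaks, genes, flags)
  with_m <- ann[ann$has_motif, , drop = FALSE]
  without_m <- ann[!ann$has_motif, , drop = FALSE]
  prox <- c(
    with_motif = if (nrow(with_m)) proximal_fraction(with_m, window_bp) else NA_real_,
    without_motif = if (nrow(without_m)) proximal_fraction(without_m, window_bp) else NA_real_
  )
  hist <- list(
    with_motif = density_summary(with_m, clamp_bp, bin_width),
    without_motif = density_summary(without_m, clamp_bp, bin_width)
  )
  contingency <- contingency_chi2(ann, window_bp)
  region_counts <- table(factor(ann$region_class,
                                levels = c("promoter", "tts", "exon",
                                           "intron", "intergenic")),
                         factor(ann$has_motif, levels = c(FALSE, TRUE)),
                         dnn = c("region", "has_motif"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(ann, file.path(out_dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(annotations = ann,
                 motif_fraction = mean(flags),
                 proximal_fraction = prox,
                 histogram = hist,
                 region_counts = region_counts,
                 contingency = contingency),
            class = "peak_report")
}
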