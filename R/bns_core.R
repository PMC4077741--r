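# Demultiplexing of barcoded selection reads and k-mer fold-enrichment of a
# selected pool over background. Enrichment is the package's definition of
# the "fold enrichment" statistic: observed window frequency in the selected
# pool divided by the expected window frequency under the background model.

#' Demultiplex barcoded reads into conditions
#'
#' Assigns each read to the condition whose 3-nt barcode equals the read's
#' first three bases exactly (3-nt barcodes leave no mismatch headroom, so
#' no rescue is attempted). Reads with unknown barcodes or with mean Phred
#' quality below `min_mean_q` go to the unassigned pool; the per-condition
#' bins plus the unassigned pool always partition the input.
#'
#' @param reads data frame from [read_fastq()].
#' @param conditions data frame with columns `barcode`, `protein_nM`,
#'   `salt_mM` (see [bns_conditions()]); barcodes must be unique.
#' @param min_mean_q minimum mean Phred score for assignment.
#' @return a list with `assigned` (a list of read data frames keyed by
#'   barcode, every condition present) and `unassigned` (a read data frame).
#' @export
demultiplex <- function(reads, conditions, min_mean_q = 0) {
  if (anyDuplicated(conditions$barcode)) {
    stop("condition barcodes must be unique", call. = FALSE)
  }
  ok_q <- if (min_mean_q > 0 && nrow(reads)) {
    mean_phred(reads$quality) >= min_mean_q
  } else rep(TRUE, nrow(reads))
  bin <- match(reads$barcode, conditions$barcode)
  keep <- ok_q & !is.na(bin)
  assigned <- lapply(conditions$barcode, function(b) {
    reads[keep & reads$barcode == b, , drop = FALSE]
  })
  names(assigned) <- conditions$barcode
  list(assigned = assigned, unassigned = reads[!keep, , drop = FALSE])
}

#' Standard ten-barcode condition table
#'
#' The canonical Bind-n-Seq design pairs ten 3-nt barcodes with a protein
#' titration (5-350 nM) and a wash-salt series (1-100 mM KCl); the first
#' five conditions belong to the full-length construct, the last five to the
#' zinc-finger construct.
#'
#' @return a data frame with columns `barcode`, `protein_nM`, `salt_mM`.
#' @export
bns_conditions <- function() {
  data.frame(
    barcode = c("ACA", "ACC", "ACG", "ACT", "AGA",
                "AGC", "AGG", "AGT", "ATA", "ATC"),
    protein_nM = c(50, 50, 50, 5, 350, 50, 50, 50, 5, 120),
    salt_mM = c(1, 50, 100, 100, 100, 1, 50, 100, 100, 100)
  )
}

#' Count k-mers in a set of sequences
#'
#' Counts every length-`k` window. Under `strand = "both"` (the default --
#' the selection substrate is double-stranded DNA) each window additionally
#' contributes one occurrence of its reverse complement, so a
#' reverse-complement-palindromic k-mer legitimately counts twice per
#' window. Windows containing `N` are skipped. `total_windows` is the number
#' of forward windows, `sum_{seq} (len - k + 1)`, regardless of strand
#' policy.
#'
#' @param seqs character vector of sequences.
#' @param k k-mer length.
#' @param strand `"both"` or `"forward"`.
#' @return an object of class `kmer_counts`: a list with `k`, `strand`,
#'   `counts` (named integer vector of observed k-mers), `total_windows`.
#' @export
count_kmers <- function(seqs, k, strand = c("both", "forward")) {
  strand <- match.arg(strand)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > 12L) stop("k-mer counting supports k <= 12", call. = FALSE)
  lens <- nchar(seqs)
  use <- lens >= k
  total_windows <- sum(pmax(lens - k + 1L, 0L))
  tab <- numeric(4^k)
  if (any(use)) {
    enc <- encode_list(seqs[use])
    # concatenate with a window over the joined vector; windows that cross a
    # sequence boundary or contain N are dropped
    v <- unlist(enc, use.names = FALSE)
    lens_u <- lengths(enc)
    ends <- cumsum(lens_u)
    starts_seq <- ends - lens_u + 1L
    # candidate window start positions within each sequence
    pos <- unlist(lapply(seq_along(lens_u), function(i) {
      starts_seq[i]:(ends[i] - k + 1L)
    }), use.names = FALSE)
    isN0 <- c(0L, cumsum(v == 5L))
    hasN <- (isN0[pos + k] - isN0[pos]) > 0L
    pos <- pos[!hasN]
    if (length(pos)) {
      vz <- v; vz[vz == 5L] <- 1L  # neutralise N codes; N windows already dropped
      code <- rep(0, length(pos))
      for (p in seq_len(k)) code <- code + (vz[pos + p - 1L] - 1) * 4^(p - 1)
      tab <- tabulate(code + 1, nbins = 4^k)
      if (strand == "both") {
        all_codes <- seq_len(4^k) - 1
        rc_perm <- revcomp_code(all_codes, k)
        tab <- tab + tab[rc_perm + 1]
      }
    }
  }
  nz <- which(tab > 0)
  counts <- as.integer(tab[nz])
  names(counts) <- if (length(nz)) decode_kmer_codes(nz - 1, k) else character(0)
  structure(list(k = k, strand = strand, counts = counts,
                 total_windows = total_windows),
            class = "kmer_counts")
}

#' Fold enrichment of k-mers in a selected pool over background
#'
#' For every k-mer with at least `min_count` occurrences in the selected
#' pool, computes `observed_freq = count / total_windows` and divides by the
#' expected frequency: either the k-mer's frequency in an empirically
#' sequenced background pool, floored at `0.5 / total_windows_background`
#' for k-mers absent from the background, or the uniform model
#' `4^-k` per window per counted strand when `background = NULL`.
#'
#' @param selected a `kmer_counts` object for the selected pool.
#' @param background a `kmer_counts` object for the unselected pool, or
#'   `NULL` for the uniform model.
#' @param min_count minimum selected-pool count for a k-mer to be reported.
#' @return a data frame with columns `kmer`, `observed_count`,
#'   `observed_freq`, `expected_freq`, `fold_enrichment`, sorted by
#'   decreasing fold enrichment with ties broken lexicographically.
#' @export
fold_enrichment <- function(selected, background = NULL, min_count = 5L) {
  stopifnot(inherits(selected, "kmer_counts"))
  if (selected$total_windows == 0L) {
    stop("selected pool has no countable windows", call. = FALSE)
  }
  counts <- selected$counts[selected$counts >= min_count]
  kmers <- names(counts)
  observed_freq <- as.numeric(counts) / selected$total_windows
  if (is.null(background)) {
    per_strand <- if (selected$strand == "both") 2 else 1
    expected_freq <- rep(per_strand * 4^(-selected$k), length(kmers))
  } else {
    stopifnot(inherits(background, "kmer_counts"))
    if (background$k != selected$k || background$strand != selected$strand) {
      stop("selected and background tables must share k and strand policy",
           call. = FALSE)
    }
    bg_count <- unname(background$counts[kmers])
    bg_count[is.na(bg_count)] <- 0
    expected_freq <- pmax(bg_count, 0.5) / background$total_windows
  }
  out <- data.frame(
    kmer = kmers,
    observed_count = as.integer(counts),
    observed_freq = observed_freq,
    expected_freq = expected_freq,
    fold_enrichment = observed_freq / expected_freq
  )
  out <- out[order(-out$fold_enrichment, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}
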