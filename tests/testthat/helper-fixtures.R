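# Shared fixtures, built in code at test time.

# the two validated consensus motifs and the EMSA probe sequences
MIZM1 <- "ATCGGTAATC"
MIZM2 <- "ATCGAT"
PROBE_P1 <- "GAATTATCGGTAATCCATCGAGGT"
PROBE_P2 <- "AGGGTTGGTATCGATTATCGAGTT"
PROBE_CP <- "CAAAAGTGCGGCTGCGTGGTGCAC"

write_tmp_lines <- function(lines) {
  path <- tempfile()
  writeLines(lines, path)
  path
}

fastq_lines <- function(seqs, ids = sprintf("r%d", seq_along(seqs)),
                        qual = strrep("I", nchar(seqs))) {
  as.vector(rbind(paste0("@", ids), seqs, "+", qual))
}

# naive quadratic k-mer counting oracle (string matching, no coding tricks)
naive_count_kmers <- function(seqs, k, strand = "both") {
  counts <- list()
  bump <- function(w) counts[[w]] <<- (counts[[w]] %||% 0L) + 1L
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("N", w)) next
      bump(w)
      if (strand == "both") bump(reverse_complement(w))
    }
  }
  unlist(counts)
}

# simple reads data frame around a set of regions
reads_df <- function(regions, barcode = "ACC") {
  data.frame(
    read_id = sprintf("r%d", seq_along(regions)),
    barcode = rep_len(barcode, length(regions)),
    region = regions,
    quality = strrep("I", nchar(regions) + 3L)
  )
}

random_dna <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# plant a word into the middle of uniform flanks
planted_reads <- function(n, word, len = 21L, seed = 1L) {
  set.seed(seed)
  w <- nchar(word)
  vapply(seq_len(n), function(i) {
    flank <- sample(c("A", "C", "G", "T"), len - w, replace = TRUE)
    at <- sample.int(len - w + 1L, 1L)
    paste(c(flank[seq_len(at - 1L)], word,
            flank[seq(at, length.out = len - w - at + 1L)]), collapse = "")
  }, "")
}
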