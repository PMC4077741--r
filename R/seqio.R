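# Readers and writers for the external formats used by the pipeline:
# 4-line FASTQ (barcoded selection reads), FASTA, MEME minimal motif format,
# BED3/BED4 peak intervals, and a refFlat-like tab-separated gene table.
# All writers emit deterministic, byte-stable output.

#' Read a barcoded Bind-n-Seq FASTQ file
#'
#' Reads 4-line FASTQ records and splits each read into its 3-nt condition
#' barcode (the first three bases) and the randomised binding region (the
#' remainder, 21 nt in the standard library design).
#'
#' @param path path to a FASTQ file (plain or gzip; `readLines` decompresses
#'   transparently).
#' @return a data frame with columns `read_id`, `barcode`, `region` and
#'   `quality` (ASCII Phred+33 string covering barcode plus region), in file
#'   order.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(read_id = character(0), barcode = character(0),
                      region = character(0), quality = character(0)))
  }
  if (n %% 4L != 0L) {
    stop(sprintf("malformed FASTQ: %d lines is not a multiple of 4", n), call. = FALSE)
  }
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ at line %d: header must start with '@'",
                 idx[bad[1L]]), call. = FALSE)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ at line %d: missing '+' separator",
                 idx[bad[1L]] + 2L), call. = FALSE)
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ at line %d: sequence/quality length mismatch",
                 idx[bad[1L]] + 3L), call. = FALSE)
  }
  bad <- which(nchar(seqs) < 4L)
  if (length(bad)) {
    stop(sprintf("malformed FASTQ at line %d: read shorter than barcode + 1",
                 idx[bad[1L]] + 1L), call. = FALSE)
  }
  seqs <- .assert_dna(seqs, "read")
  data.frame(
    read_id = sub("^@", "", sub("\\s.*$", "", hdr)),
    barcode = substr(seqs, 1L, 3L),
    region = substr(seqs, 4L, nchar(seqs)),
    quality = qual
  )
}

#' Write reads as 4-line FASTQ
#'
#' @param reads a data frame as returned by [read_fastq()]; the written
#'   sequence is `paste0(barcode, region)`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- paste0(reads$barcode, reads$region)
  qual <- if ("quality" %in% names(reads)) reads$quality else
    strrep("I", nchar(seqs))
  out <- character(4L * nrow(reads))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$read_id)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- seqs
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Read and write FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that return plain named character vectors.
#' Lowercase input is uppercased; characters outside A, C, G, T, N are
#' rejected.
#'
#' @param path file path.
#' @return `read_fasta`: a named character vector of uppercase sequences in
#'   file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  .assert_dna(out)
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @param width line-wrap width for the sequence lines.
#' @return `write_fasta`: `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- .assert_dna(seqs)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses the MEME minimal motif interchange format (version line, optional
#' alphabet/strands/background lines, `MOTIF` blocks each with a
#' `letter-probability matrix` header). This is the single motif interchange
#' format used by the package, matching the MEME/Tomtom/FIMO ecosystem.
#'
#' @param path path to a MEME-format motif file.
#' @return a list of [bns_motif] objects.
#' @export
read_meme <- function(path) {
  lines <- trimws(readLines(path))
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(lines[bg_at[1L] + 1L], "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks[c(FALSE, TRUE)]))
    keys <- toks[c(TRUE, FALSE)]
    if (anyNA(vals) || !setequal(keys, .BASES)) {
      stop("malformed background frequency line", call. = FALSE)
    }
    bg <- vals[match(.BASES, keys)]
  }
  starts <- grep("^MOTIF\\s", lines)
  motifs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    id <- strsplit(lines[starts[i]], "\\s+")[[1L]][2L]
    at <- starts[i] + 1L
    while (at <= length(lines) && !grepl("^letter-probability matrix", lines[at])) {
      at <- at + 1L
      if (at > length(lines)) stop(sprintf("motif %s: no letter-probability matrix", id), call. = FALSE)
    }
    hdr <- lines[at]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr)) {
      as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr))
    } else NULL
    rows <- lines[(at + 1L):(at + w)]
    mat <- do.call(rbind, lapply(seq_along(rows), function(j) {
      v <- suppressWarnings(as.numeric(strsplit(rows[j], "\\s+")[[1L]]))
      if (length(v) != 4L || anyNA(v)) {
        stop(sprintf("motif %s row %d: expected 4 numeric probabilities", id, j),
             call. = FALSE)
      }
      v
    }))
    if (any(abs(rowSums(mat) - 1) > 1e-3)) {
      stop(sprintf("motif %s: probability row sums outside 1 +/- 1e-3", id),
           call. = FALSE)
    }
    motifs[[i]] <- bns_motif(probs = mat, background = bg, nsites = nsites, id = id)
  }
  motifs
}

#' @rdname read_meme
#' @param motifs a list of [bns_motif] objects (a single motif is accepted).
#' @return `write_meme`: `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  if (inherits(motifs, "bns_motif")) motifs <- list(motifs)
  bg <- motifs[[1L]]$background
  out <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", .BASES, bg), collapse = " "), ""
  )
  for (m in motifs) {
    out <- c(out,
      paste("MOTIF", m$id),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= %s E= 0",
              m$width, format(m$nsites, digits = 8)),
      apply(m$probs, 1L, function(r) paste(sprintf("%10.6f", r), collapse = " ")),
      "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read peak intervals from a BED file
#'
#' BED3/BED4, tab-separated, 0-based half-open coordinates. Peaks lacking a
#' name column get synthesised ids `peak_1`, `peak_2`, ...
#'
#' @param path path to a BED file.
#' @return a data frame with columns `chrom`, `start`, `end`, `peak_id`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), peak_id = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      stop(sprintf("BED line %d: fewer than 3 columns", i), call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("BED line %d: non-integer coordinate", i), call. = FALSE)
    }
    if (start < 0L || end <= start) {
      stop(sprintf("BED line %d: requires 0 <= start < end", i), call. = FALSE)
    }
    list(chrom = f[1L], start = start, end = end,
         peak_id = if (length(f) >= 4L && nzchar(f[4L])) f[4L] else paste0("peak_", i))
  })
  data.frame(
    chrom = vapply(out, `[[`, "", "chrom"),
    start = vapply(out, `[[`, 0L, "start"),
    end = vapply(out, `[[`, 0L, "end"),
    peak_id = vapply(out, `[[`, "", "peak_id")
  )
}

#' Write peaks as BED4
#'
#' @param peaks data frame with columns `chrom`, `start`, `end`, `peak_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", peaks$chrom, peaks$start, peaks$end,
                     peaks$peak_id), path)
  invisible(path)
}

#' Read a refFlat-like gene table
#'
#' Tab-separated columns `geneName`, `chrom`, `strand`, `txStart`, `txEnd`,
#' `exonCount`, `exonStarts`, `exonEnds` (comma-separated exon lists), with
#' an optional header line. Coordinates are 0-based half-open, as in refFlat.
#' The TSS of a `+` gene is `txStart`; of a `-` gene, `txEnd - 1` (the last
#' transcribed 0-based coordinate), so distances for both strands live in
#' one coordinate frame.
#'
#' @param path path to the gene table.
#' @return a data frame with columns `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end` and list columns `exon_starts`, `exon_ends`.
#' @export
read_gene_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("geneName", lines[1L])) lines <- lines[-1L]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 8L) stop(sprintf("gene table line %d: expected 8 columns", i), call. = FALSE)
    if (!f[3L] %in% c("+", "-")) {
      stop(sprintf("gene table line %d: unknown strand '%s'", i, f[3L]), call. = FALSE)
    }
    tx_start <- as.integer(f[4L]); tx_end <- as.integer(f[5L])
    if (is.na(tx_start) || is.na(tx_end) || tx_end <= tx_start) {
      stop(sprintf("gene table line %d: requires txStart < txEnd", i), call. = FALSE)
    }
    es <- as.integer(strsplit(f[7L], ",")[[1L]])
    ee <- as.integer(strsplit(f[8L], ",")[[1L]])
    if (length(es) != length(ee) || length(es) != as.integer(f[6L])) {
      stop(sprintf("gene table line %d: exon list lengths disagree with exonCount", i),
           call. = FALSE)
    }
    if (any(ee <= es) || is.unsorted(es, strictly = TRUE) ||
        any(es[-1L] < ee[-length(ee)]) ||
        es[1L] < tx_start || ee[length(ee)] > tx_end) {
      stop(sprintf("gene table line %d: exons must be sorted, non-overlapping, within the transcript", i),
           call. = FALSE)
    }
    list(gene_id = f[1L], chrom = f[2L], strand = f[3L],
         tx_start = tx_start, tx_end = tx_end,
         exon_starts = es, exon_ends = ee)
  })
  out <- data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    tx_start = vapply(rows, `[[`, 0L, "tx_start"),
    tx_end = vapply(rows, `[[`, 0L, "tx_end")
  )
  out$exon_starts <- lapply(rows, `[[`, "exon_starts")
  out$exon_ends <- lapply(rows, `[[`, "exon_ends")
  out
}

#' Write a gene table in the refFlat-like dialect read by [read_gene_table()]
#'
#' @param genes data frame as returned by [read_gene_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$gene_id[i], genes$chrom[i], genes$strand[i],
          genes$tx_start[i], genes$tx_end[i],
          length(genes$exon_starts[[i]]),
          paste(genes$exon_starts[[i]], collapse = ","),
          paste(genes$exon_ends[[i]], collapse = ","),
          sep = "\t")
  }, "")
  writeLines(c("geneName\tchrom\tstrand\ttxStart\ttxEnd\texonCount\texonStarts\texonEnds",
               out), path)
  invisible(path)
}

#' Transcription start / termination sites of gene models
#'
#' @param genes gene table from [read_gene_table()].
#' @return integer vector of 0-based genomic positions.
#' @export
tss_position <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
}

#' @rdname tss_position
#' @export
tts_position <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_end - 1L, genes$tx_start)
}
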