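# Low-level sequence machinery shared by all modules.
#
# Sequences are handled externally as uppercase character strings over
# {A,C,G,T,N} and internally as integer codes 1:4 (A,C,G,T) with 5L for N.
# All hot loops (k-mer coding, PWM window scoring) work on integer matrices
# of equal-length sequences so they vectorise.

.BASES <- c("A", "C", "G", "T")

.base_lut <- local({
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt("N")] <- 5L; lut[utf8ToInt("n")] <- 5L
  lut
})

# complement in integer code space; N stays N
.comp_lut <- c(4L, 3L, 2L, 1L, 5L)

.assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTNacgtn]", x)
  if (any(bad)) {
    stop(sprintf("invalid %s: characters outside {A,C,G,T,N} in %s",
                 what, paste(utils::head(which(bad), 3L), collapse = ", ")),
         call. = FALSE)
  }
  toupper(x)
}

# character vector of equal-length sequences -> n x L integer matrix
encode_matrix <- function(x) {
  L <- unique(nchar(x))
  if (length(L) != 1L) stop("sequences must all have the same length", call. = FALSE)
  n <- length(x)
  if (n == 0L) return(matrix(integer(0), 0L, 0L))
  v <- .base_lut[utf8ToInt(paste(x, collapse = ""))]
  if (anyNA(v)) stop("characters outside {A,C,G,T,N}", call. = FALSE)
  matrix(v, nrow = n, ncol = L, byrow = TRUE)
}

# character vector (any lengths) -> list of integer vectors
encode_list <- function(x) {
  lapply(x, function(s) {
    v <- .base_lut[utf8ToInt(s)]
    if (anyNA(v)) stop("characters outside {A,C,G,T,N}", call. = FALSE)
    v
  })
}

# integer matrix -> character vector
decode_matrix <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  letters4 <- c(.BASES, "N")
  cols <- lapply(seq_len(ncol(m)), function(j) letters4[m[, j]])
  do.call(paste0, cols)
}

decode_vector <- function(v) paste(c(.BASES, "N")[v], collapse = "")

#' Reverse complement
#'
#' Watson-Crick reverse complement. For character vectors this delegates to
#' [Biostrings::reverseComplement()]; `N` maps to `N`. For motif objects the
#' probability/count matrices are reversed row-wise with complement columns
#' swapped, so `consensus(reverse_complement(m))` equals
#' `reverse_complement(consensus(m))`.
#'
#' @param x a character vector of DNA sequences, or a [bns_motif] object.
#' @param ... unused.
#' @return an object of the same type as `x`.
#' @examples
#' reverse_complement("ATCGGTAATC")  # "GATTACCGAT"
#' @export
reverse_complement <- function(x, ...) UseMethod("reverse_complement")

#' @export
reverse_complement.character <- function(x, ...) {
  x <- .assert_dna(x)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# uniform random sequences in integer code space (no N)
random_seq_matrix <- function(n, len) {
  matrix(sample.int(4L, n * len, replace = TRUE), nrow = n, ncol = len)
}

# Encode every length-k window of an integer matrix (no N allowed) as a
# base-4 integer code: code = sum_p (b_p - 1) * 4^(p-1), 0-based.
# Returns an n x (L - k + 1) numeric matrix of codes.
window_codes <- function(m, k) {
  L <- ncol(m)
  noff <- L - k + 1L
  pow <- 4^(seq_len(k) - 1)
  code <- matrix(0, nrow(m), noff)
  first <- rep(0, nrow(m))
  for (p in seq_len(k)) first <- first + (m[, p] - 1) * pow[p]
  code[, 1L] <- first
  if (noff > 1L) {
    for (j in 2:noff) {
      code[, j] <- (code[, j - 1L] - (m[, j - 1L] - 1)) / 4 +
        (m[, j + k - 1L] - 1) * pow[k]
    }
  }
  code
}

# code of the reverse complement of a word given its forward code
revcomp_code <- function(code, k) {
  rc <- rep(0, length(code))
  for (p in seq_len(k)) {
    digit <- code %% 4
    code <- (code - digit) %/% 4
    rc <- rc + (3 - digit) * 4^(k - p)  # complement digit, reversed weight
  }
  rc
}

# decode integer codes (0-based) back to k-mer strings
decode_kmer_codes <- function(code, k) {
  out <- matrix("", length(code), k)
  for (p in seq_len(k)) {
    digit <- code %% 4
    out[, p] <- .BASES[digit + 1]
    code <- (code - digit) %/% 4
  }
  do.call(paste0, lapply(seq_len(k), function(p) out[, p]))
}

encode_kmer <- function(s) {
  v <- .base_lut[utf8ToInt(s)]
  sum((v - 1) * 4^(seq_along(v) - 1))
}

# mean Phred score of an ASCII (offset 33) quality string
mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q) - 33L), numeric(1), USE.NAMES = FALSE)
}

hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# all sequences at Hamming distance exactly 1 from s
hamming1_neighbours <- function(s) {
  v <- strsplit(s, "")[[1]]
  out <- character(0)
  for (i in seq_along(v)) {
    for (b in setdiff(.BASES, v[i])) {
      w <- v; w[i] <- b
      out <- c(out, paste(w, collapse = ""))
    }
  }
  out
}
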