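#' Position weight matrix motifs
#'
#' A `bns_motif` holds a DNA binding motif as a width x 4 probability matrix
#' over the bases A, C, G, T (rows are motif positions, rows sum to 1),
#' optionally together with the underlying count matrix, an effective site
#' count (`nsites`), a background base composition, and a fold-enrichment
#' score attached by the discovery pipeline.
#'
#' @param probs width x 4 numeric matrix of base probabilities; rows must sum
#'   to 1 within 1e-6 (rows are renormalised to machine precision).
#' @param counts optional width x 4 non-negative count matrix.
#' @param background length-4 base composition of the background model, in
#'   A, C, G, T order; must be strictly positive and sum to 1.
#' @param nsites effective number of sites the motif was built from.
#' @param id motif identifier.
#' @param enrichment_score optional fold-enrichment ratio attached by
#'   [discover_motifs()].
#' @return an object of class `bns_motif`.
#' @seealso [motif_from_consensus()], [read_meme()], [log_odds()]
#' @export
bns_motif <- function(probs = NULL, counts = NULL,
                      background = rep(0.25, 4), nsites = NULL,
                      id = "motif", enrichment_score = NA_real_) {
  if (is.null(probs) && is.null(counts)) {
    stop("one of `probs` or `counts` is required", call. = FALSE)
  }
  if (is.null(probs)) {
    counts <- as.matrix(counts)
    probs <- counts / rowSums(counts)
  }
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("probability matrix must have 4 columns (A,C,G,T)", call. = FALSE)
  if (any(probs < 0)) stop("negative probabilities", call. = FALSE)
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-3)) {
    stop("probability rows must sum to 1 (tolerance 1e-3)", call. = FALSE)
  }
  probs <- probs / rs
  colnames(probs) <- .BASES
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0)) {
    stop("background must be 4 strictly positive frequencies", call. = FALSE)
  }
  background <- background / sum(background)
  names(background) <- .BASES
  if (is.null(nsites)) {
    nsites <- if (!is.null(counts)) max(rowSums(counts)) else 20
  }
  structure(
    list(id = id, width = nrow(probs), probs = probs, counts = counts,
         background = background, nsites = nsites,
         enrichment_score = enrichment_score),
    class = "bns_motif"
  )
}

#' Build a motif from a consensus word
#'
#' Each column assigns probability `p0` to the consensus base and
#' `(1 - p0) / 3` to the other three bases. With `p0 = 1` the motif is the
#' exact consensus (scoring then relies on the pseudocount in
#' [log_odds()]).
#'
#' @param consensus a DNA word over A, C, G, T.
#' @param p0 probability of the consensus base per column, in (0.25, 1].
#' @inheritParams bns_motif
#' @return a `bns_motif`.
#' @examples
#' motif_from_consensus("ATCGAT", p0 = 0.7)
#' @export
motif_from_consensus <- function(consensus, p0 = 0.85, nsites = 20,
                                 background = rep(0.25, 4),
                                 id = consensus) {
  consensus <- .assert_dna(consensus, "consensus")
  if (grepl("N", consensus)) stop("consensus may not contain N", call. = FALSE)
  if (p0 <= 0.25 || p0 > 1) stop("p0 must lie in (0.25, 1]", call. = FALSE)
  v <- .base_lut[utf8ToInt(consensus)]
  w <- length(v)
  probs <- matrix((1 - p0) / 3, w, 4)
  probs[cbind(seq_len(w), v)] <- p0
  bns_motif(probs = probs, background = background, nsites = nsites, id = id)
}

#' Consensus sequence of a motif
#'
#' The per-column most probable base; ties resolve in A, C, G, T order.
#'
#' @param motif a `bns_motif`.
#' @return a character scalar of length `motif$width`.
#' @export
consensus <- function(motif) {
  stopifnot(inherits(motif, "bns_motif"))
  idx <- apply(motif$probs, 1L, which.max)
  paste(.BASES[idx], collapse = "")
}

#' @export
reverse_complement.bns_motif <- function(x, ...) {
  flip <- function(m) {
    if (is.null(m)) return(NULL)
    m <- m[rev(seq_len(nrow(m))), c(4L, 3L, 2L, 1L), drop = FALSE]
    colnames(m) <- .BASES
    m
  }
  x$probs <- flip(x$probs)
  x$counts <- flip(x$counts)
  x$background <- stats::setNames(x$background[c(4L, 3L, 2L, 1L)], .BASES)
  x
}

#' @export
print.bns_motif <- function(x, ...) {
  cat(sprintf("<bns_motif> %s  width=%d  nsites=%s  consensus=%s",
              x$id, x$width, format(x$nsites, digits = 4), consensus(x)))
  if (!is.na(x$enrichment_score)) {
    cat(sprintf("  enrichment=%.2f", x$enrichment_score))
  }
  cat("\n")
  print(round(x$probs, 3))
  invisible(x)
}
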