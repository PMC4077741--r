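# PWM scoring machinery: log-odds matrices, exact null score distributions
# by position-wise dynamic programming on a discretised score grid (the
# FIMO-style construction that makes a p-value cutoff exact), both-strand
# scanning, per-sequence occurrence fractions, and motif-motif comparison.
#
# Scores are discretised once per matrix; scanning and the null
# distribution share the same integer grid, so the p-value of a scanned
# window is the exact tail probability of its quantised score.

#' Log-odds scoring matrix of a motif
#'
#' Entry `[p, b] = log2(smoothed_prob / background_prob)` in bits, with
#' FIMO-style pseudocount smoothing
#' `smoothed = (prob + pseudocount * background) / (1 + pseudocount)`.
#'
#' @param motif a [bns_motif].
#' @param background length-4 background frequencies (A, C, G, T); must be
#'   strictly positive. Defaults to the motif's own background.
#' @param pseudocount smoothing mass added per column.
#' @return a width x 4 numeric matrix in bits, with the background and
#'   pseudocount attached as attributes.
#' @examples
#' m <- motif_from_consensus("ATCGAT", p0 = 1)
#' log_odds(m, pseudocount = 0.01)[1, ]  # A entry ~ log2(0.9925/0.25)
#' @export
log_odds <- function(motif, background = motif$background, pseudocount = 0.01) {
  background <- as.numeric(background)
  if (any(background <= 0)) stop("background entries must be positive", call. = FALSE)
  background <- background / sum(background)
  sm <- sweep(motif$probs, 2L, pseudocount * background, "+") / (1 + pseudocount)
  mat <- log2(sweep(sm, 2L, background, "/"))
  colnames(mat) <- .BASES
  attr(mat, "background") <- background
  attr(mat, "pseudocount") <- pseudocount
  mat
}

# reverse-complement a log-odds (or probability) matrix: scoring the minus
# strand of a sequence with M is scoring the plus strand with flip(M)
flip_matrix <- function(mat) {
  out <- mat[rev(seq_len(nrow(mat))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- .BASES
  out
}

#' Exact null score distribution of a scoring matrix
#'
#' Discretises the matrix onto an integer grid of `granularity` bins over
#' the attainable score range, then convolves the per-position score
#' distributions under the background model. The resulting PMF is exact on
#' the grid, so `p(s)` (the tail probability of scores `>= s`) agrees with
#' brute-force enumeration over all `4^width` words quantised to the same
#' grid.
#'
#' @param score_matrix width x 4 matrix from [log_odds()].
#' @param background length-4 background frequencies; defaults to the
#'   background the matrix was built with.
#' @param granularity number of grid bins over the score range (>= 1000).
#' @return an object of class `score_null` with elements `qmat` (the
#'   quantised integer matrix used for scanning), `step`, `offset` (bits of
#'   integer score 0), `pmf` and `tail` (indexed by integer score + 1).
#' @export
null_score_distribution <- function(score_matrix,
                                    background = attr(score_matrix, "background"),
                                    granularity = 1000L) {
  if (any(!is.finite(score_matrix))) {
    stop("score matrix has non-finite entries; apply a pseudocount upstream",
         call. = FALSE)
  }
  if (is.null(background)) background <- rep(0.25, 4)
  background <- as.numeric(background) / sum(background)
  granularity <- as.integer(granularity)
  if (granularity < 1000L) stop("granularity must be >= 1000 bins", call. = FALSE)
  rmin <- apply(score_matrix, 1L, min)
  rmax <- apply(score_matrix, 1L, max)
  range_total <- sum(rmax) - sum(rmin)
  step <- if (range_total > 0) range_total / granularity else 1
  qmat <- round(sweep(score_matrix, 1L, rmin, "-") / step)
  storage.mode(qmat) <- "integer"
  max_int <- sum(apply(qmat, 1L, max))
  pmf <- numeric(max_int + 1L)
  pmf[1L] <- 1
  hi <- 0L
  for (p in seq_len(nrow(qmat))) {
    newpmf <- numeric(max_int + 1L)
    for (b in 1:4) {
      q <- qmat[p, b]
      idx <- seq_len(hi + 1L)
      newpmf[idx + q] <- newpmf[idx + q] + pmf[idx] * background[b]
    }
    pmf <- newpmf
    hi <- hi + max(qmat[p, ])
  }
  tail <- rev(cumsum(rev(pmf)))
  tail <- pmin(tail, 1)
  structure(
    list(qmat = qmat, step = step, offset = sum(rmin), pmf = pmf, tail = tail,
         granularity = granularity, background = background),
    class = "score_null"
  )
}

#' @export
print.score_null <- function(x, ...) {
  cat(sprintf("<score_null> width=%d step=%.4g bits range=[%.3f, %.3f]\n",
              nrow(x$qmat), x$step, x$offset,
              x$offset + x$step * (length(x$pmf) - 1L)))
  invisible(x)
}

# p-value of integer grid scores under a score_null
null_pvalue <- function(null, int_score) {
  null$tail[pmin(int_score, length(null$tail) - 1L) + 1L]
}

# smallest integer grid score whose tail probability is < p_threshold,
# or NA if no score reaches it
null_threshold <- function(null, p_threshold) {
  ok <- which(null$tail < p_threshold)
  if (!length(ok)) NA_integer_ else ok[1L] - 1L
}

# Integer window scores of an n x L code matrix against a quantised matrix.
# Windows containing N (code 5) score NA. Returns n x (L - w + 1) matrix.
quantised_window_scores <- function(m, qmat) {
  w <- nrow(qmat)
  noff <- ncol(m) - w + 1L
  if (noff < 1L) return(matrix(NA_real_, nrow(m), 0L))
  lut <- cbind(qmat, NA_integer_)  # 5th column: N
  S <- matrix(0, nrow(m), noff)
  for (j in seq_len(noff)) {
    s <- lut[1L, m[, j]]
    if (w > 1L) for (p in 2:w) s <- s + lut[p, m[, j + p - 1L]]
    S[, j] <- s
  }
  S
}

#' Scan sequences for motif occurrences at an exact p-value threshold
#'
#' Scores every window of every sequence (both strands by default) with the
#' quantised log-odds matrix and reports windows whose exact null p-value is
#' below `p_threshold`. Minus-strand matches are reported at the forward
#' coordinate of the window start. Sequences shorter than the motif yield no
#' matches. A strict-consensus width-6 matrix against a uniform background
#' has a minimum attainable p-value of `4^-6 ~ 2.4e-4`, so narrow motifs
#' need a threshold above that to be findable at all.
#'
#' @param seqs named character vector of sequences (names become `seq_id`;
#'   unnamed input gets `seq_1`, `seq_2`, ...).
#' @param motif a [bns_motif].
#' @param p_threshold report windows with p-value strictly below this
#'   (default `1e-4`, the conventional FIMO cutoff).
#' @param strand `"both"` or `"forward"`.
#' @param background background model for scoring and the null; defaults to
#'   uniform.
#' @param pseudocount,granularity passed to [log_odds()] /
#'   [null_score_distribution()].
#' @return a data frame with columns `seq_id`, `start` (0-based), `stop`
#'   (1 past the end), `strand`, `score` (bits, on the quantised grid),
#'   `p_value`, `matched_sequence`, sorted by (sequence, start, strand).
#' @export
scan_sequences <- function(seqs, motif, p_threshold = 1e-4,
                           strand = c("both", "forward"),
                           background = rep(0.25, 4),
                           pseudocount = 0.01, granularity = 1000L) {
  strand <- match.arg(strand)
  if (p_threshold <= 0 || p_threshold >= 1) {
    stop("p_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  w <- motif$width
  lodds <- log_odds(motif, background, pseudocount)
  nulls <- list("+" = null_score_distribution(lodds, background, granularity))
  if (strand == "both") {
    nulls[["-"]] <- null_score_distribution(flip_matrix(lodds), background, granularity)
  }
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      stop = integer(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0),
                      matched_sequence = character(0))
  keep <- nchar(seqs) >= w
  if (!any(keep)) return(empty)
  lens <- nchar(seqs)[keep]
  groups <- split(which(keep), lens)
  res <- list()
  for (g in groups) {
    m <- encode_matrix(unname(seqs[g]))
    for (st in names(nulls)) {
      null <- nulls[[st]]
      thr <- null_threshold(null, p_threshold)
      if (is.na(thr)) next
      S <- quantised_window_scores(m, null$qmat)
      hit <- which(!is.na(S) & S >= thr, arr.ind = TRUE)
      if (!nrow(hit)) next
      iseq <- g[hit[, 1L]]
      start0 <- hit[, 2L] - 1L
      word <- substr(seqs[iseq], start0 + 1L, start0 + w)
      if (st == "-") word <- reverse_complement(word)
      res[[length(res) + 1L]] <- data.frame(
        seq_id = names(seqs)[iseq],
        seq_index = iseq,
        start = start0,
        stop = start0 + w,
        strand = st,
        score = null$offset + null$step * S[hit],
        p_value = null_pvalue(null, S[hit]),
        matched_sequence = unname(word)
      )
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$seq_index, out$start, out$strand), , drop = FALSE]
  out$seq_index <- NULL
  rownames(out) <- NULL
  out
}

#' Fraction of sequences containing at least one motif match
#'
#' The "peaks containing an instance of the motif" statistic: a sequence
#' counts once however many windows (or strands, for palindromic motifs)
#' match.
#'
#' @inheritParams scan_sequences
#' @return a proportion in `[0, 1]`.
#' @export
fraction_with_match <- function(seqs, motif, p_threshold = 1e-4,
                                strand = "both",
                                background = rep(0.25, 4),
                                pseudocount = 0.01, granularity = 1000L) {
  if (length(seqs) == 0L) stop("empty sequence set", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  hits <- scan_sequences(seqs, motif, p_threshold, strand, background,
                         pseudocount, granularity)
  length(unique(hits$seq_id)) / length(seqs)
}

pearson4 <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) 0 else sum(a * b) / den
}

# best ungapped alignment of two probability matrices: mean per-column
# Pearson correlation, maximised over offsets with >= min_overlap columns
best_alignment <- function(qp, tp, min_overlap = 4L) {
  wq <- nrow(qp); wt <- nrow(tp)
  best <- list(score = -Inf, offset = NA_integer_)
  for (off in (-(wt - min_overlap)):(wq - min_overlap)) {
    i1 <- max(1L, 1L + off); i2 <- min(wq, wt + off)
    if (i2 - i1 + 1L < min_overlap) next
    idx <- i1:i2
    r <- vapply(idx, function(i) pearson4(qp[i, ], tp[i - off, ]), numeric(1))
    sc <- mean(r)
    if (sc > best$score) best <- list(score = sc, offset = off)
  }
  best
}

#' Compare a query motif against a set of target motifs
#'
#' For each target, scores every ungapped offset with at least four
#' overlapping columns, in the forward and (optionally) reverse-complement
#' orientation of the target. Column similarity is the Pearson correlation
#' of the probability 4-vectors; the alignment score is the mean similarity
#' over the overlap. Significance comes from a seeded permutation null: the
#' target's columns are shuffled `n_permutations` times and the best
#' alignment score recomputed, giving
#' `p = (1 + #{perm >= observed}) / (n_permutations + 1)` and
#' `E = p * n_targets`.
#'
#' @param query a [bns_motif] with width >= 4.
#' @param targets a list of [bns_motif] objects (a single motif is
#'   accepted).
#' @param orientation `"both"` or `"forward"`.
#' @param n_permutations number of column shuffles (>= 1000 recommended for
#'   reported p-values).
#' @param seed integer seed for the permutation null.
#' @return a data frame with one row per target: `query_id`, `target_id`,
#'   `offset` (position of the target's first column relative to the
#'   query's), `orientation`, `score`, `p_value`, `e_value`, sorted by
#'   p-value then target id.
#' @export
compare_motifs <- function(query, targets, orientation = c("both", "forward"),
                           n_permutations = 1000L, seed = 1L) {
  orientation <- match.arg(orientation)
  if (inherits(targets, "bns_motif")) targets <- list(targets)
  if (query$width < 4L) stop("query width must be >= 4", call. = FALSE)
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  qp <- query$probs
  n_targets <- length(targets)
  rows <- vector("list", n_targets)
  set.seed(seed)
  for (ti in seq_len(n_targets)) {
    tg <- targets[[ti]]
    obs_f <- best_alignment(qp, tg$probs)
    obs <- c(obs_f, orientation = "forward")
    if (orientation == "both") {
      obs_r <- best_alignment(qp, flip_matrix(tg$probs))
      if (obs_r$score > obs_f$score) {
        obs <- c(obs_r, orientation = "reverse_complement")
      }
    }
    perm_best <- vapply(seq_len(n_permutations), function(i) {
      sh <- tg$probs[sample.int(tg$width), , drop = FALSE]
      b <- best_alignment(qp, sh)$score
      if (orientation == "both") b <- max(b, best_alignment(qp, flip_matrix(sh))$score)
      b
    }, numeric(1))
    p <- (1 + sum(perm_best >= obs$score)) / (n_permutations + 1)
    rows[[ti]] <- data.frame(
      query_id = query$id, target_id = tg$id,
      offset = obs$offset, orientation = obs$orientation,
      score = obs$score, p_value = p, e_value = p * n_targets
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Best both-strand log-odds window score per sequence (exact arithmetic, not
# quantised). Used by match-back and the selection simulator. Sequences must
# share one length; returns a numeric vector.
best_window_scores <- function(m, lodds) {
  fwd <- exact_window_scores(m, lodds)
  rev <- exact_window_scores(m, flip_matrix(lodds))
  both <- cbind(fwd, rev)
  do.call(pmax, c(as.data.frame(both), na.rm = TRUE))
}

exact_window_scores <- function(m, lodds) {
  w <- nrow(lodds)
  noff <- ncol(m) - w + 1L
  lut <- cbind(lodds, NA_real_)
  S <- matrix(0, nrow(m), noff)
  for (j in seq_len(noff)) {
    s <- lut[1L, m[, j]]
    if (w > 1L) for (p in 2:w) s <- s + lut[p, m[, j + p - 1L]]
    S[, j] <- s
  }
  S
}

# maximum attainable score of a log-odds matrix
max_score <- function(lodds) sum(apply(lodds, 1L, max))
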