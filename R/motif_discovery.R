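# De-novo motif elicitation: PWM seeds from enriched k-mers, a
# zero-or-one-occurrence-per-sequence (ZOOPS) EM fitted on sampled read
# clusters, match-back of intermediate motifs to the full read set for
# refinement rounds, and ranking of final motifs by k-mer fold enrichment.

#' Seed motifs from enriched k-mers
#'
#' For each of the top `n_seeds` records, builds a PWM whose columns give
#' probability `p0` to the k-mer's base and `(1 - p0) / 3` to the others.
#'
#' @param records enrichment table from [fold_enrichment()].
#' @param n_seeds number of seeds (capped at the number of records).
#' @param p0 per-column consensus probability, in (0.25, 1).
#' @return a list of [bns_motif] objects.
#' @export
seed_motifs <- function(records, n_seeds = 5L, p0 = 0.7) {
  if (nrow(records) == 0L) stop("empty enrichment record list", call. = FALSE)
  stopifnot(n_seeds >= 1L)
  top <- utils::head(records, n_seeds)
  lapply(seq_len(nrow(top)), function(i) {
    m <- motif_from_consensus(top$kmer[i], p0 = p0, id = paste0("seed_", top$kmer[i]))
    m$enrichment_score <- top$fold_enrichment[i]
    m
  })
}

# natural-log probability-ratio window scores (site vs background), floored
# so exact-consensus seeds with zero cells stay finite
.zoops_ratio_matrix <- function(probs, background, floor = 1e-6) {
  p <- pmax(probs, floor)
  p <- p / rowSums(p)
  log(sweep(p, 2L, background, "/"))
}

#' Fit a zero-or-one-occurrence-per-sequence (ZOOPS) motif model by EM
#'
#' Each sequence carries at most one motif site; a prior `gamma` gives the
#' probability that a sequence has a site, uniform over offsets and (by
#' default) strands. The E-step computes the posterior over \{no site\} and
#' every (offset, strand); the M-step re-estimates the PWM from expected
#' aligned counts plus a pseudocount, and `gamma` as the mean site
#' posterior. The observed-data log-likelihood is non-decreasing across
#' iterations (a property asserted by the test suite).
#'
#' @param seqs character vector of sequences, each at least as long as the
#'   initial motif.
#' @param init initial [bns_motif].
#' @param gamma0 initial site prior in (0, 1).
#' @param tol convergence: maximum absolute change in any probability cell.
#' @param max_iter iteration cap.
#' @param pseudocount count added per PWM cell in the M-step.
#' @param background length-4 background frequencies.
#' @param strand `"both"` or `"forward"`.
#' @return a list of class `zoops_fit`: `motif`, `gamma`, `log_likelihood`
#'   (trajectory in nats, one entry per iteration), `n_iterations`,
#'   `converged`.
#' @export
em_zoops <- function(seqs, init, gamma0 = 0.5, tol = 1e-4, max_iter = 100L,
                     pseudocount = 0.1, background = rep(0.25, 4),
                     strand = c("both", "forward")) {
  strand <- match.arg(strand)
  w <- init$width
  if (any(nchar(seqs) < w)) {
    stop("all sequences must be at least as long as the motif", call. = FALSE)
  }
  background <- as.numeric(background) / sum(background)
  groups <- split(seq_along(seqs), nchar(seqs))
  mats <- lapply(groups, function(g) encode_matrix(unname(seqs[g])))
  n <- length(seqs)
  probs <- init$probs
  gamma <- gamma0
  ll_trace <- numeric(0)
  converged <- FALSE
  n_strand <- if (strand == "both") 2L else 1L
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    ratio <- .zoops_ratio_matrix(probs, background)
    counts <- matrix(pseudocount, w, 4L)
    z_site_total <- 0
    ll <- 0
    for (m in mats) {
      noff <- ncol(m) - w + 1L
      n_here <- nrow(m)
      Sf <- exact_window_scores(m, ratio)
      LR <- exp(Sf)
      if (strand == "both") {
        Sr <- exact_window_scores(m, flip_matrix(ratio))
        LR <- cbind(LR, exp(Sr))
      }
      prior <- gamma / (n_strand * noff)
      denom <- (1 - gamma) + prior * rowSums(LR)
      ll <- ll + sum(log(denom))
      z <- LR * (prior / denom)  # n x (n_strand * noff) posteriors
      z_site_total <- z_site_total + sum(z)
      # expected aligned counts via crossproducts with the base indicator
      # matrices: counts[p, b] sums z over the diagonal band j, j + p - 1
      jf <- seq_len(noff)
      for (b in 1:4) {
        Ib <- m == b
        Cf <- crossprod(z[, jf, drop = FALSE], Ib)  # noff x L
        for (p in seq_len(w)) {
          counts[p, b] <- counts[p, b] + sum(Cf[cbind(jf, jf + p - 1L)])
        }
        if (strand == "both") {
          # minus-strand window at offset j aligns motif position p with
          # the complement of sequence position j + w - p
          Ic <- m == .comp_lut[b]
          Cr <- crossprod(z[, noff + jf, drop = FALSE], Ic)
          for (p in seq_len(w)) {
            counts[p, b] <- counts[p, b] + sum(Cr[cbind(jf, jf + w - p)])
          }
        }
      }
    }
    # constant background term of the likelihood is omitted; it does not
    # depend on the parameters and so cannot break monotonicity
    ll_trace <- c(ll_trace, ll)
    new_probs <- counts / rowSums(counts)
    new_gamma <- min(max(z_site_total / n, 1e-6), 1 - 1e-6)
    delta <- max(abs(new_probs - probs))
    probs <- new_probs
    gamma <- new_gamma
    if (delta < tol) { converged <- TRUE; break }
  }
  motif <- bns_motif(probs = probs, counts = counts,
                     background = background,
                     nsites = z_site_total, id = init$id)
  structure(list(motif = motif, gamma = gamma, log_likelihood = ll_trace,
                 n_iterations = iter, converged = converged),
            class = "zoops_fit")
}

#' Match a motif back against the full read set
#'
#' Returns the reads whose best both-strand log-odds window score reaches
#' `score_fraction` times the motif's maximum attainable score -- the
#' match-back step that collects reads for a refinement round of EM.
#' `score_fraction = 1` demands a perfect consensus site; because log-odds
#' scores of background windows are negative, lowering the fraction towards
#' 0 relaxes the threshold only to "some positive-scoring window", not to
#' the whole read set.
#'
#' @param seqs character vector of reads.
#' @param motif a [bns_motif].
#' @param score_fraction fraction of the maximum attainable score, in
#'   (0, 1].
#' @param background,pseudocount scoring parameters.
#' @return the matching subset of `seqs`.
#' @export
match_back <- function(seqs, motif, score_fraction = 0.8,
                       background = rep(0.25, 4), pseudocount = 0.01) {
  if (score_fraction <= 0 || score_fraction > 1) {
    stop("score_fraction must lie in (0, 1]", call. = FALSE)
  }
  lodds <- log_odds(motif, background, pseudocount)
  thr <- score_fraction * max_score(lodds) - 1e-9
  keep <- logical(length(seqs))
  groups <- split(seq_along(seqs), nchar(seqs))
  tables <- if (motif$width <= 12L) score_tables(lodds)
  for (g in groups) {
    if (nchar(seqs[g[1L]]) < motif$width) next
    m <- encode_matrix(unname(seqs[g]))
    if (!is.null(tables) && !anyNA(m) && !any(m == 5L)) {
      codes <- window_codes(m, motif$width)
      best <- rep(-Inf, nrow(m))
      for (j in seq_len(ncol(codes))) {
        cj <- codes[, j] + 1
        best <- pmax(best, tables$fwd[cj], tables$rc[cj])
      }
      keep[g] <- best >= thr
    } else {
      keep[g] <- best_window_scores(m, lodds) >= thr
    }
  }
  seqs[keep]
}

#' De-novo motif discovery on a selected read pool
#'
#' The full elicitation pipeline, per motif width: (1) k-mer fold
#' enrichment over the uniform background on all reads; (2) PWM seeds from
#' the top enriched k-mers; (3) ZOOPS EM on a randomly sampled cluster of
#' `cluster_size` reads; (4) match-back of the intermediate motif against
#' all reads and (5) EM re-fit on the matched subset, repeating (4)-(5) for
#' `n_rounds`; (6) each final motif is assigned the maximum fold enrichment
#' among k-mers within Hamming distance 1 of its consensus; (7) motifs of
#' equal width whose consensus (or its reverse complement) lie within
#' Hamming distance 1 of a better-scoring motif are removed, and each kept
#' consensus is canonicalised to the lexicographically smaller of itself
#' and its reverse complement; (8) the top `top_n` motifs by enrichment
#' score are returned.
#'
#' @param seqs character vector of reads (binding regions, barcodes
#'   removed).
#' @param widths motif widths to search (within the conventional 6-30
#'   bound; the fast scorer caps them at 12).
#' @param cluster_size EM sample size (10,000 in the standard protocol;
#'   smaller inputs use all reads).
#' @param n_rounds match-back refinement rounds.
#' @param n_seeds seeds per width.
#' @param p0 seed sharpness.
#' @param min_count minimum k-mer count for the enrichment table.
#' @param score_fraction match-back threshold.
#' @param top_n motifs to report.
#' @param seed integer seed controlling cluster sampling.
#' @param ... further arguments passed to [em_zoops()].
#' @return a list of [bns_motif] objects sorted by decreasing
#'   `enrichment_score`.
#' @export
discover_motifs <- function(seqs, widths = c(6L, 8L, 10L),
                            cluster_size = 10000L, n_rounds = 3L,
                            n_seeds = 5L, p0 = 0.7, min_count = 5L,
                            score_fraction = 0.8, top_n = 5L, seed = 1L,
                            ...) {
  if (length(seqs) == 0L) stop("empty read set", call. = FALSE)
  if (any(widths > 12L)) stop("widths above 12 are not supported", call. = FALSE)
  set.seed(seed)
  found <- list()
  for (k in sort(widths)) {
    if (k > min(nchar(seqs))) next
    enr <- fold_enrichment(count_kmers(seqs, k, "both"), NULL, min_count)
    if (nrow(enr) == 0L) next
    fe <- stats::setNames(enr$fold_enrichment, enr$kmer)
    seeds <- seed_motifs(enr, n_seeds, p0)
    for (sd in seeds) {
      idx <- if (length(seqs) > cluster_size) {
        sample.int(length(seqs), cluster_size)
      } else seq_along(seqs)
      fit <- em_zoops(seqs[idx], sd, ...)
      for (round in seq_len(n_rounds)) {
        matched <- match_back(seqs, fit$motif, score_fraction)
        if (length(matched) < 50L) break
        if (length(matched) > cluster_size) {
          matched <- matched[sample.int(length(matched), cluster_size)]
        }
        fit <- em_zoops(matched, fit$motif, ...)
      }
      motif <- fit$motif
      cons <- consensus(motif)
      neigh <- c(cons, hamming1_neighbours(cons))
      score <- suppressWarnings(max(fe[neigh], na.rm = TRUE))
      motif$enrichment_score <- if (is.finite(score)) score else 0
      motif$id <- sprintf("w%d_%s", k, cons)
      found[[length(found) + 1L]] <- motif
    }
  }
  if (!length(found)) return(list())
  found <- found[order(-vapply(found, `[[`, 0, "enrichment_score"),
                       vapply(found, consensus, ""))]
  kept <- list()
  for (m in found) {
    cons <- consensus(m)
    rc <- reverse_complement(cons)
    dup <- any(vapply(kept, function(km) {
      kc <- consensus(km)
      nchar(kc) == nchar(cons) &&
        (hamming(kc, cons) <= 1L || hamming(kc, rc) <= 1L)
    }, logical(1)))
    if (dup) next
    if (rc < cons) {
      m <- reverse_complement(m)
      m$id <- sprintf("w%d_%s", m$width, consensus(m))
    }
    kept[[length(kept) + 1L]] <- m
    if (length(kept) >= top_n) break
  }
  kept
}
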