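# Parametric simulator of Bind-n-Seq selection libraries and of synthetic
# genome / gene-table / peak sets. The selection model is an explicit
# occupancy-based stand-in for the wet selection: one interpretable
# parameter per phenomenon (binding-energy scale, half-saturation,
# nonspecific floor, wash decay, carryover), not a claim about the original
# experiment's physical constants.

#' Parametric selection model for Bind-n-Seq simulation
#'
#' Retention of a candidate random region `s` with best both-strand
#' log-odds score `b(s)` (bits, against a uniform background) under protein
#' concentration `P` (nM) and wash salt `S` (mM) is
#' `p = min(1, p_spec + p_ns)` with
#'
#' * `p_spec = exp(-w_spec * S) * max_m P / (P + (K_half / affinity_m) *
#'   exp(lambda * (b_max_m - b_m(s))))` -- Hill-1 occupancy whose effective
#'   dissociation constant rises exponentially with the binding-energy
#'   deficit of the best site;
#' * `p_ns = alpha * P / (P + K_half) * exp(-w_nonspec * S) + epsilon` --
#'   sequence-independent sticking plus a constant carryover floor.
#'
#' With `P = 0` specific retention is 0; nonspecific washes out faster than
#' specific binding (`w_nonspec > w_spec`), which makes enrichment grow
#' with salt stringency, while the carryover floor plus the progressive
#' recruitment of weak partial matches at high protein makes enrichment
#' peak at moderate protein concentration.
#'
#' The defaults were fixed once from the closed-form enrichment oracle
#' ([expected_fold_enrichment()]) so that a 5/50/350 nM titration at 50 mM
#' salt peaks at 50 nM, with consensus fold enrichments spanning the
#' several-fold to few-tens-fold regime reported for this assay class.
#'
#' @param motifs a [bns_motif] or list of them: the planted binding
#'   specificities. Defaults to the exact-consensus motif ATCGGTAATC.
#' @param affinity relative affinity (>= 0) per motif; scales down the
#'   half-saturation constant.
#' @param lambda binding energy per bit of log-odds score deficit (1/bits).
#' @param K_half half-saturation protein concentration (nM).
#' @param alpha nonspecific retention amplitude in `[0, 1]`.
#' @param w_spec,w_nonspec wash decay rates (1/mM), `w_nonspec > w_spec`.
#' @param epsilon carryover floor probability.
#' @param pseudocount smoothing used when scoring candidates.
#' @return an object of class `selection_model`.
#' @export
selection_model <- function(motifs = motif_from_consensus("ATCGGTAATC", p0 = 1),
                            affinity = 1,
                            lambda = 0.14,
                            K_half = 50,
                            alpha = 0.01,
                            w_spec = 0.005,
                            w_nonspec = 0.02,
                            epsilon = 0.005,
                            pseudocount = 0.01) {
  if (inherits(motifs, "bns_motif")) motifs <- list(motifs)
  affinity <- rep_len(affinity, length(motifs))
  stopifnot(length(motifs) >= 1L, all(affinity >= 0), lambda >= 0,
            K_half > 0, alpha >= 0, alpha <= 1,
            w_spec >= 0, w_nonspec > w_spec, epsilon >= 0, epsilon <= 1)
  if (any(vapply(motifs, `[[`, 0L, "width") > 12L)) {
    stop("planted motifs wider than 12 bp are not supported by the fast scorer",
         call. = FALSE)
  }
  lodds <- lapply(motifs, log_odds, background = rep(0.25, 4),
                  pseudocount = pseudocount)
  structure(
    list(motifs = motifs, affinity = affinity, lambda = lambda,
         K_half = K_half, alpha = alpha, w_spec = w_spec,
         w_nonspec = w_nonspec, epsilon = epsilon,
         pseudocount = pseudocount, lodds = lodds,
         b_max = vapply(lodds, max_score, numeric(1))),
    class = "selection_model"
  )
}

# full score lookup tables over all 4^w words for each planted motif:
# tab_fwd[code+1] = score of the word, tab_rc[code+1] = score of its
# reverse complement (so forward window codes serve both strands)
score_tables <- function(lodds) {
  build <- function(mat) {
    t <- 0
    for (p in seq_len(nrow(mat))) t <- as.vector(outer(t, mat[p, ], "+"))
    t
  }
  list(fwd = build(lodds), rc = build(flip_matrix(lodds)))
}

# best both-strand window score of every row of an integer code matrix,
# per planted motif; returns n x n_motifs matrix
best_scores_fast <- function(m, model, tables) {
  out <- matrix(-Inf, nrow(m), length(model$lodds))
  for (mi in seq_along(model$lodds)) {
    w <- nrow(model$lodds[[mi]])
    codes <- window_codes(m, w)
    tf <- tables[[mi]]$fwd; tr <- tables[[mi]]$rc
    best <- rep(-Inf, nrow(m))
    for (j in seq_len(ncol(codes))) {
      cj <- codes[, j] + 1
      best <- pmax(best, tf[cj], tr[cj])
    }
    out[, mi] <- best
  }
  out
}

# retention probability given the per-motif best scores
retention_probability <- function(model, best, protein, salt) {
  p_spec <- 0
  for (mi in seq_len(ncol(best))) {
    K_eff <- (model$K_half / model$affinity[mi]) *
      exp(model$lambda * (model$b_max[mi] - best[, mi]))
    p_spec <- pmax(p_spec, protein / (protein + K_eff))
  }
  p_spec <- p_spec * exp(-model$w_spec * salt)
  p_ns <- model$alpha * protein / (protein + model$K_half) *
    exp(-model$w_nonspec * salt) + model$epsilon
  pmin(1, p_spec + p_ns)
}

#' Uniform random background library
#'
#' i.i.d. uniform sequences over A, C, G, T; a pure function of the seed.
#'
#' @param n number of sequences.
#' @param length sequence length in bp (21 in the standard library design).
#' @param seed integer seed.
#' @return a character vector of `n` sequences.
#' @export
simulate_background <- function(n, length = 21L, seed = 1L) {
  stopifnot(n > 0)
  set.seed(seed)
  decode_matrix(random_seq_matrix(n, length))
}

#' Simulate retained Bind-n-Seq libraries under a selection model
#'
#' For each condition, draws uniform random candidate regions in chunks,
#' scores each candidate's best both-strand log-odds match to every planted
#' motif, retains it with the model's retention probability, and stops once
#' `n_selected` reads are retained. Retained reads get the condition's
#' barcode prepended and constant Q40 qualities (quality modelling is not
#' part of the analysed computation). Deterministic given `seed`.
#'
#' @param conditions data frame with columns `barcode`, `protein_nM`,
#'   `salt_mM`; barcodes must be unique.
#' @param model a [selection_model()].
#' @param n_selected retained reads per condition (the assay yields roughly
#'   100,000 reads per sample).
#' @param n_background size of the emitted unselected background pool.
#' @param region_length randomised region length (bp).
#' @param seed integer seed.
#' @param chunk_size candidate draws per chunk.
#' @param max_factor give up (with an error) after `max_factor * n_selected`
#'   candidates fail to fill a condition.
#' @return a list of class `bns_simulation`: `reads` (named list, one read
#'   data frame per barcode with columns `read_id`, `barcode`, `region`,
#'   `quality`), `background` (character vector), `conditions`, `model`.
#' @export
simulate_bns_library <- function(conditions, model = selection_model(),
                                 n_selected = 1e5, n_background = 1e5,
                                 region_length = 21L, seed = 1L,
                                 chunk_size = 5e5, max_factor = 2000) {
  if (anyDuplicated(conditions$barcode)) {
    stop("duplicate barcodes in conditions", call. = FALSE)
  }
  min_w <- min(vapply(model$motifs, `[[`, 0L, "width"))
  if (region_length < min_w) {
    stop("region_length shorter than a planted motif", call. = FALSE)
  }
  set.seed(seed)
  tables <- lapply(model$lodds, score_tables)
  qual <- strrep("I", region_length + 3L)
  reads <- vector("list", nrow(conditions))
  names(reads) <- conditions$barcode
  for (ci in seq_len(nrow(conditions))) {
    P <- conditions$protein_nM[ci]; S <- conditions$salt_mM[ci]
    kept <- matrix(integer(0), 0L, region_length)
    drawn <- 0
    while (nrow(kept) < n_selected) {
      if (drawn > max_factor * n_selected) {
        stop(sprintf("condition %s: retention too low to fill %d reads",
                     conditions$barcode[ci], n_selected), call. = FALSE)
      }
      m <- random_seq_matrix(chunk_size, region_length)
      drawn <- drawn + chunk_size
      best <- best_scores_fast(m, model, tables)
      p <- retention_probability(model, best, P, S)
      keep <- stats::runif(chunk_size) < p
      kept <- rbind(kept, m[keep, , drop = FALSE])
    }
    kept <- kept[seq_len(n_selected), , drop = FALSE]
    reads[[ci]] <- data.frame(
      read_id = sprintf("%s_%06d", conditions$barcode[ci], seq_len(n_selected)),
      barcode = conditions$barcode[ci],
      region = decode_matrix(kept),
      quality = qual
    )
  }
  background <- decode_matrix(random_seq_matrix(n_background, region_length))
  structure(list(reads = reads, background = background,
                 conditions = conditions, model = model, seed = seed),
            class = "bns_simulation")
}

#' Closed-form expected fold enrichment of the planted consensus
#'
#' The analytic counterpart of the simulator: the expected fold enrichment
#' of a planted motif's exact consensus k-mer in the retained pool equals
#' the retention probability of a consensus-bearing read divided by the
#' mean retention over the background pool, which is estimated here by
#' Monte Carlo over `n_mc` uniform candidates. Used as the independent
#' oracle for the enrichment-vs-protein titration.
#'
#' @param model a [selection_model()].
#' @param protein protein concentration, nM.
#' @param salt wash salt, mM.
#' @param which_motif index of the planted motif to evaluate.
#' @param region_length region length, bp.
#' @param n_mc Monte Carlo sample size for the background mean.
#' @param seed integer seed.
#' @return the expected fold enrichment (dimensionless).
#' @export
expected_fold_enrichment <- function(model, protein, salt, which_motif = 1L,
                                     region_length = 21L, n_mc = 2e5,
                                     seed = 1L) {
  set.seed(seed)
  tables <- lapply(model$lodds, score_tables)
  m <- random_seq_matrix(n_mc, region_length)
  best <- best_scores_fast(m, model, tables)
  p_bg <- mean(retention_probability(model, best, protein, salt))
  b_top <- matrix(rep(model$b_max, each = 1L), 1L)
  # consensus-bearing read: best score = b_max for the chosen motif, at
  # background level for the others
  b_read <- matrix(apply(best, 2L, stats::median), 1L)
  b_read[1L, which_motif] <- model$b_max[which_motif]
  p_m <- retention_probability(model, b_read, protein, salt)
  as.numeric(p_m / p_bg)
}

#' Synthetic genome, gene table and peak set with a planted motif
#'
#' Generates a random genome with non-overlapping gene models laid out in
#' fixed-size slots, then places peaks so that motif-free peaks are
#' TSS-proximal (midpoint within 1.5 kb of the nearest TSS) with
#' probability `proximal_bias` while motif-containing peaks are proximal
#' with probability `1 - proximal_bias` -- the structure in which a motif
#' occurs preferentially in TSS-distal peaks. Each motif-containing peak
#' carries exactly one planted consensus instance at a random offset and
#' strand; accidental consensus occurrences elsewhere in a peak are mutated
#' away so the truth table is exact.
#'
#' @param seed integer seed.
#' @param n_genes,n_peaks number of gene models / peaks.
#' @param motif a [bns_motif] (its consensus is planted) or a consensus
#'   string.
#' @param frac_motif_peaks fraction of peaks that carry the motif.
#' @param proximal_bias probability in `[0, 1]` that a motif-free peak is
#'   proximal (and that a motif-containing peak is distal).
#' @param peak_width peak width, bp.
#' @param slot_size genome bp reserved per gene model.
#' @return a list of class `synthetic_genome`: `genome` (named character),
#'   `genes`, `peaks`, `truth` (data frame with `peak_id`, `has_motif`,
#'   `planted_offset`, `strand`, `true_tss_distance`).
#' @export
simulate_genome_peaks <- function(seed = 1L, n_genes = 60L, n_peaks = 400L,
                                  motif = "ATCGGTAATC",
                                  frac_motif_peaks = 0.5,
                                  proximal_bias = 0.9,
                                  peak_width = 200L,
                                  slot_size = 20000L) {
  stopifnot(frac_motif_peaks >= 0, frac_motif_peaks <= 1,
            proximal_bias >= 0, proximal_bias <= 1)
  cons <- if (inherits(motif, "bns_motif")) consensus(motif) else
    .assert_dna(motif, "motif consensus")
  wm <- nchar(cons)
  if (peak_width < wm) stop("peak_width shorter than the motif", call. = FALSE)
  set.seed(seed)
  margin <- 60000L
  glen <- n_genes * slot_size + 2L * margin
  gv <- sample.int(4L, glen, replace = TRUE)

  # gene models: one per slot, 2-8 kb, random strand, 2-4 exons
  tx_len <- sample(2000:8000, n_genes, replace = TRUE)
  slot0 <- margin + (seq_len(n_genes) - 1L) * slot_size
  tx_start <- slot0 + sample(0:(slot_size - 9000L), n_genes, replace = TRUE)
  tx_end <- tx_start + tx_len
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  exons <- lapply(seq_len(n_genes), function(i) {
    k <- sample(2:4, 1L)
    cuts <- sort(sample(seq(200L, tx_len[i] - 200L, by = 50L), 2L * (k - 1L)))
    es <- tx_start[i] + c(0L, cuts[c(FALSE, TRUE)])
    ee <- tx_start[i] + c(cuts[c(TRUE, FALSE)], tx_len[i])
    list(starts = es, ends = ee)
  })
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = "chr1", strand = strand,
    tx_start = tx_start, tx_end = tx_end
  )
  genes$exon_starts <- lapply(exons, `[[`, "starts")
  genes$exon_ends <- lapply(exons, `[[`, "ends")
  tss <- tss_position(genes)

  # brute-force signed strand-adjusted nearest-TSS distance (construction
  # truth; independent of annotate_peaks)
  true_dist <- function(mid) {
    d <- abs(mid - tss)
    i <- order(d, pmin(genes$tx_start, genes$tx_end), genes$gene_id)[1L]
    if (genes$strand[i] == "+") mid - tss[i] else tss[i] - mid
  }

  n_motif <- round(frac_motif_peaks * n_peaks)
  has_motif <- c(rep(TRUE, n_motif), rep(FALSE, n_peaks - n_motif))
  proximal <- stats::runif(n_peaks) < ifelse(has_motif, 1 - proximal_bias,
                                             proximal_bias)
  half <- peak_width %/% 2L
  mids <- integer(n_peaks)
  for (i in seq_len(n_peaks)) {
    for (attempt in 1:200) {
      anchor <- tss[sample.int(n_genes, 1L)]
      off <- if (proximal[i]) {
        sample(-1400:1400, 1L)
      } else {
        sample(c(-1L, 1L), 1L) * sample(4000:45000, 1L)
      }
      mid <- anchor + off
      if (mid - half < 0L || mid + half >= glen) next
      d <- min(abs(mid - tss))
      if (proximal[i] && d <= 1500L) break
      if (!proximal[i] && d > 1500L) break
    }
    if (attempt == 200L) stop("could not place peaks; genome too crowded", call. = FALSE)
    mids[i] <- mid
  }
  starts <- mids - half
  ends <- starts + peak_width

  # plant one consensus instance per motif peak, then scrub accidental
  # occurrences so exact string search reproduces the truth flags
  cons_code <- .base_lut[utf8ToInt(cons)]
  rc_code <- .comp_lut[rev(cons_code)]
  planted_offset <- rep(NA_integer_, n_peaks)
  planted_strand <- rep(NA_character_, n_peaks)
  for (i in which(has_motif)) {
    off <- sample.int(peak_width - wm + 1L, 1L) - 1L
    st <- sample(c("+", "-"), 1L)
    word <- if (st == "+") cons_code else rc_code
    gv[(starts[i] + off + 1L):(starts[i] + off + wm)] <- word
    planted_offset[i] <- off
    planted_strand[i] <- st
  }
  find_hits <- function(v, word) {
    if (length(v) < length(word)) return(integer(0))
    hit <- rep(TRUE, length(v) - length(word) + 1L)
    for (p in seq_along(word)) {
      hit <- hit & v[seq_along(hit) + p - 1L] == word[p]
    }
    which(hit)
  }
  for (pass in 1:10) {
    dirty <- FALSE
    for (i in seq_len(n_peaks)) {
      pv <- gv[(starts[i] + 1L):ends[i]]
      hits <- sort(unique(c(find_hits(pv, cons_code), find_hits(pv, rc_code))))
      if (has_motif[i]) hits <- setdiff(hits, planted_offset[i] + 1L)
      for (h in hits) {
        pos <- starts[i] + h + wm %/% 2L  # mutate the middle base
        gv[pos] <- sample(setdiff(1:4, gv[pos]), 1L)
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }

  peaks <- data.frame(chrom = "chr1", start = starts, end = ends,
                      peak_id = sprintf("peak_%03d", seq_len(n_peaks)))
  truth <- data.frame(
    peak_id = peaks$peak_id,
    has_motif = has_motif,
    planted_offset = planted_offset,
    strand = planted_strand,
    true_tss_distance = vapply(mids, true_dist, numeric(1))
  )
  structure(list(genome = stats::setNames(decode_vector(gv), "chr1"),
                 genes = genes, peaks = peaks, truth = truth, seed = seed),
            class = "synthetic_genome")
}
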