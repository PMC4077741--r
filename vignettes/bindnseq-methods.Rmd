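---
title: "Methods: Bind-n-Seq motif discovery and peak reanalysis"
author: "bindnseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bind-n-Seq motif discovery and peak reanalysis}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindnseq)
```

# Scope

Bind-n-Seq is an in-vitro selection assay for protein-DNA binding
specificity: a tagged DNA-binding protein is incubated with a pool of
double-stranded oligonucleotides carrying a randomised 21-bp region behind
a 3-nt condition barcode, bound fragments are washed under varying salt
stringency, eluted, and sequenced to roughly 100,000 reads per condition.
`bindnseq` implements the downstream computation end to end:

1. **seqio** -- FASTQ/FASTA/BED/MEME-minimal/gene-table readers and
   writers, and the barcode/region read split;
2. **synthetic data** -- an occupancy-based simulator of the selection,
   plus a synthetic genome/peak generator with a planted motif;
3. **core enrichment** -- demultiplexing and k-mer fold enrichment of a
   selected pool over background;
4. **motif discovery** -- PWM seeds from enriched k-mers, a ZOOPS
   (zero-or-one-occurrence-per-sequence) EM fitted on sampled read
   clusters, match-back refinement rounds, and ranking by enrichment;
5. **motif analysis** -- log-odds scanning with exact dynamic-programming
   p-values, per-sequence occurrence fractions, and motif-motif
   comparison;
6. **peak genomics** -- distance-to-TSS annotation, region classification,
   and the 2x2 chi-squared test of motif presence versus promoter
   proximity.

# The selection model

The simulator is an explicit stand-in for the wet selection, not a claim
about the original experiment's physical constants. A candidate region
$s$ with best both-strand log-odds score $b(s)$ (bits, uniform
background) against the planted motif is retained with probability
$\min(1, p_\mathrm{spec} + p_\mathrm{ns})$, where with protein
concentration $P$ (nM) and wash salt $S$ (mM):

$$p_\mathrm{spec} = e^{-w_\mathrm{spec} S}\,
  \frac{P}{P + K_{1/2}\, e^{\lambda\,(b_\mathrm{max} - b(s))}},
  \qquad
  p_\mathrm{ns} = \alpha\,\frac{P}{P + K_{1/2}}\, e^{-w_\mathrm{nonspec} S}
  + \varepsilon.$$

One interpretable parameter per phenomenon:

| parameter | default | units | role |
|---|---|---|---|
| $\lambda$ | 0.14 | 1/bit | binding energy per bit of score deficit |
| $K_{1/2}$ | 50 | nM | half-saturation of the consensus site |
| $\alpha$ | 0.01 | -- | nonspecific sticking amplitude |
| $w_\mathrm{spec}$ | 0.005 | 1/mM | wash decay of specific complexes |
| $w_\mathrm{nonspec}$ | 0.02 | 1/mM | wash decay of nonspecific complexes |
| $\varepsilon$ | 0.005 | -- | salt- and protein-independent carryover |

The default planted motif is the exact consensus ATCGGTAATC; mismatch
penalties then come from the pseudocount-smoothed log-odds matrix.

**Why enrichment peaks at moderate protein.** Fold enrichment of the
consensus k-mer is (to first order) the retention probability of a
consensus-bearing read divided by the mean retention of the background
pool (`expected_fold_enrichment()` computes exactly this and serves as
the titration oracle). Three regimes shape the titration at fixed salt:

* at low protein, specific occupancy is small and retention is dominated
  by the carryover floor $\varepsilon$, which caps enrichment;
* at moderate protein, the consensus site approaches saturation while
  weak partial matches are still mostly unbound -- enrichment peaks;
* at high protein, sequences with one-to-several mismatches (whose
  effective dissociation constants are $K_{1/2} e^{\lambda \Delta b}$)
  are progressively recruited, inflating the background mean and pulling
  enrichment back down.

With the defaults, the closed form gives folds of roughly 13/34/18 at
5/50/350 nM and 50 mM salt; the simulator reproduces this within
sampling error. The defaults were fixed once, from the closed form,
before the acceptance tests were written, and have not been revisited.

A consequence worth stating explicitly: with the nonspecific pathway
switched off ($\alpha = \varepsilon = 0$) enrichment is monotonically
*decreasing* in protein, because every sequence's occupancy ratio to the
consensus shrinks toward 1 as occupancy saturates. Selectivity is
maximal at low protein; it is the carryover floor that produces the
rising low-protein arm seen in real titrations. The property suite tests
this direction.

**What the generator does not emulate:** sequencing error, PCR
amplification bias, quality-score variation (reads are constant Q40 --
the platform's own filtering is upstream of the analysed computation),
paired-end layouts, or cooperative/multi-site binding. A green test on
simulated libraries therefore establishes correctness of the
computation under the stated selection mechanism, not fidelity to every
artefact of a real sequencing run.

# Motif discovery

Per width (defaults 6, 8, 10, within the conventional 6--30 bound):
k-mer fold enrichment on all reads (both strands; the substrate is
double-stranded, so a palindromic k-mer legitimately counts twice per
window), PWM seeds with probability $p_0 = 0.7$ on the k-mer base, a
ZOOPS EM on a sampled cluster of 10,000 reads, then `n_rounds = 3`
rounds of match-back (reads scoring at least 0.8 of the motif's maximum
attainable log-odds) and EM re-fit. Final motifs get the maximum fold
enrichment among k-mers within Hamming distance 1 of their consensus --
the package's operational definition of a motif-level enrichment score
-- and reverse-complement duplicates collapse to the lexicographically
smaller consensus.

EM settings: pseudocount 0.1 per cell, $\gamma_0 = 0.5$, tolerance
$10^{-4}$ on the maximum probability change, 100 iterations. The
observed-data log-likelihood is non-decreasing every iteration (the test
suite asserts this on every fitted trajectory; the E/M steps were
verified against a brute-force enumeration of the posterior).

**Null behaviour of the EM.** An unregularised ZOOPS EM run on pure
background does not drive $\gamma$ to zero: it drifts to a diffuse,
typically reverse-complement-palindromic motif of ~1--2 bits total
information content, with $\gamma$ anywhere between 0.2 and 0.7,
because a diffuse component can absorb arbitrary background mass (the
known diffuse-motif degeneracy; MEME counters it with its E-value
objective, which is out of scope here). The discriminating signature of
a null fit is therefore low information content, and at the pipeline
level the enrichment score: discovery on pure background yields scores
below 2, versus 25-35 for a planted motif under default selection.

Match-back thresholds are fractions of the *maximum* attainable score.
Because background windows score negative, lowering the fraction to 0
relaxes the criterion only to "any positive-scoring window", never to
the whole read set; an early range-interpolation variant that did reach
the whole read set turned 0.8 into a ~2-bit threshold for sharp
matrices and measurably degraded recovery of planted PWMs, so the
max-score definition stands.

# Scanning and exact p-values

Log-odds matrices use FIMO-style smoothing,
$\tilde p = (p + c\,\mathrm{bg})/(1 + c)$ with $c = 0.01$ by default.
For p-values the matrix is discretised onto an integer grid (1000 bins
over the attainable range by default, scores rounded); the null score
PMF is the position-wise convolution of the per-column distributions
under the background, and scanning uses the *same* quantised matrix, so
a reported p-value is the exact tail probability of the reported score.
The suite checks DP-vs-enumeration equality for widths up to 6 and
calibration of the realised match rate on $10^7$ uniform windows at
$p = 10^{-3}$ and $10^{-4}$.

Two discreteness effects matter in practice. A strict-consensus width-6
matrix attains a minimum p-value of $4^{-6} \approx 2.4\times10^{-4}$,
so narrow motifs are unfindable at the conventional $10^{-4}$ cutoff --
scan them at $10^{-3}$. And a two-level consensus-like matrix has only
width + 1 achievable scores, so its realised match rate can sit well
below a requested threshold; calibration statements are made for
matrices with heterogeneous columns (dense score grids), where a
granularity of 5000 keeps the discretisation gap far inside the
binomial noise band.

Motif-motif comparison scores every ungapped offset with at least four
overlapping columns, both orientations, by mean per-column Pearson
correlation of probability vectors (one of Tomtom's published metrics);
significance comes from a seeded column-shuffle permutation null with
$p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(n + 1)$, which is
super-uniform by construction, and $E = p \times$ number of targets.
Uniform columns get correlation 0; orientation ties (palindromes) keep
the forward orientation.

# Peak annotation conventions

Coordinates are 0-based half-open throughout; a minus-strand gene's TSS
is `txEnd - 1`, so distances live in one frame for both strands.
Distance is measured from the peak midpoint, $\lfloor(start+end)/2\rfloor$,
to the nearest TSS by absolute distance (ties: lower gene coordinate,
then gene id), signed negative upstream of the gene. Region classes are
evaluated at the midpoint with priority promoter ($-1$ kb to $+100$ bp
around the TSS) > TTS region ($-100$ bp to $+1$ kb) > exon > intron >
intergenic, so the classes partition the peak set. "Proximal" means
within 1.5 kb absolute; density summaries clamp distances at $\pm50$ kb
into symmetric bins with the boundary values tallied in the outermost
bins. The chi-squared test is Pearson's without continuity correction
(df = 1); degenerate margins return a flag instead of a p-value. No
multiple-testing correction is applied to scan p-values: occurrence
fractions inherit the per-match convention of the standard
$p < 10^{-4}$ workflow.

The synthetic genome generator places motif-free peaks TSS-proximal
with probability `proximal_bias` and motif-bearing peaks proximal with
the complementary probability, plants exactly one consensus instance
per motif peak, and mutates away accidental consensus occurrences so
exact string search reproduces its truth table -- which is what lets
the annotation stack be tested against construction-time truth rather
than against itself.

# Numerical and degenerate-input choices

* Sequences are validated against {A,C,G,T,N}; lowercase is uppercased,
  anything else is rejected rather than masked.
* Windows containing N are skipped in counting and score NA in scans.
* k-mers absent from an empirical background get a 0.5-count floor, so
  fold enrichments stay finite.
* Enrichment ties break lexicographically; consensus ties break in
  A,C,G,T order; orientation ties keep forward -- all so that equal
  seeds give byte-equal outputs.
* The fast simulator scores candidates through full lookup tables over
  all $4^w$ words, capping planted motif widths at 12 (ample for the
  6-10 bp motifs this assay class reports).
* Candidate generation is rejection sampling; a condition whose
  retention cannot fill the requested read count within
  `max_factor * n_selected` draws raises an error rather than looping.

# Known limitations

Match-back uses a score-fraction threshold rather than a p-value; the
EM fits one motif at a time with no erasure, so secondary motifs
surface only through different seeds or widths; the comparison null
shuffles whole columns and so conditions on column composition; Homer
feature parity (CpG islands, repeats, UTR/CDS subdivision) is out of
scope; and reproduction of the published ChIP-seq percentages requires
the deposited peak sets and matching annotation releases, which are
deliberately not downloaded here -- the in-package evidence is
property- and simulation-based.
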