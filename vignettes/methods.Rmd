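---
title: "Models and procedures behind imtkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and procedures behind imtkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
each stage of the toolkit: what is computed, which parameters matter, how
degenerate inputs are handled, and what the synthetic-data tests do and do
not demonstrate about real data.

## Combinatorial barcodes and demultiplexing

A combinatorial split-pool library identifies each nucleus by the
concatenation of four barcode fragments read as a contiguous prefix of the
barcode-bearing mate: three 6-bp bead-round segments followed by one 10-bp
Tn5-plate segment, 28 bp in total. The assay literature does not pin down
whether the plate segment precedes or follows the bead segments within the
prefix; we default to bead rounds 1–3 then Tn5 and make the layout fully
configurable (`read_structure()`), since only segment offsets and lengths
matter downstream. The canonical cell identifier joins the corrected
segments in read order with `"+"`; any fixed, injective join would do.

Three decisions shape the demultiplexer:

* **Quality statistic.** "Barcode quality below 10" is read as the
  *minimum* base quality over the 28 prefix bases — the strictest
  interpretation, which never passes a read a laxer statistic would
  reject. A mean-quality mode is provided (`stat = "mean"`). The gate is
  `>= 10`: a read whose worst barcode base is exactly Phred 10 passes.
* **Per-segment correction.** Each fragment is corrected independently
  against its own whitelist, allowing one mismatch per fragment, so up to
  four total mismatches can be rescued on one read. A segment corrects
  only to a *unique* whitelist entry at Hamming distance 1; zero neighbors
  is "uncorrectable", two or more is "ambiguous", and ambiguity is never
  resolved by quality weighting because no tie-break rule is defensible
  without calibration data.
* **Order of operations.** Quality gating precedes correction; the
  rejection categories (too-short, quality, uncorrectable, ambiguous)
  partition the input exactly, which the tests assert.

A whitelist whose minimum pairwise Hamming distance is at least 3 makes
one-mismatch correction unambiguous by the triangle inequality; the
whitelist builder measures every segment set and warns below that floor
rather than failing, because real bead lots occasionally violate it and
the demultiplexer degrades gracefully (ambiguous reads are dropped, never
misassigned).

## Fragments, the Tn5 shift and per-cell QC

Tn5 tagmentation inserts two adapters 9 bp apart, so the outer template
coordinates overestimate the accessible interval. All coordinates are
0-based half-open (BED convention). For a raw template `[start, end)` the
corrected fragment is `[start + 4, end − 5)`; the insertion *sites* used
for TSS scoring are the corrected `start` and `end − 1`. Pairs whose
corrected interval is empty (raw length < 10) are dropped and counted.
Records are filtered at mapping quality ≥ 2 before pairing, mirroring
common practice for this assay; the duplicate key is (chromosome, start,
end, barcode) — the barcode is part of the key, so identical coordinates
from two nuclei are distinct fragments. chrY and chrM are excluded by
default with case-insensitive matching.

The TSS enrichment score follows the standard per-cell fold-over-flank
recipe: insertion sites are aggregated in strand-oriented ±2000-bp windows
around every TSS; the score is the mean per-base count in the central
101 bp divided by the mean over the outermost 100 bp of each flank, with
the background floored at 0.1 so that cells with no flank insertions get a
large (not infinite) score. All four constants are arguments. Cell
selection is strict and conjunctive: TSS score > 10 *and* unique
fragments > 1500.

## Count-matrix processing

Normalization is `ln(count / cell_total × 10⁴ + 1)` — i.e. ln(CPM/100+1) —
which is scale-invariant within a cell and maps zero counts to zero. Cells
with fewer than 500 transcripts, or more than 20% of transcripts from
mitochondria-encoded genes (identified by a configurable `mt-` prefix),
are removed first; a zero-total cell reaching the normalizer is an error
directing the user to QC. The highly-variable-gene recipe bins genes by
mean normalized expression into 20 equal-occupancy bins, computes
dispersion = variance/mean, z-scores it within each bin and takes the top
*n* with ties broken by gene identifier (so the selection is a
deterministic function of the matrix). We deliberately do not regress out
total counts or clip scaled values before scoring; scores operate on the
ln-normalized matrix directly, a documented divergence kept for
transparency of the score definitions.

Gene-set scores use the control-bin construction: the score is the mean
over set genes minus the mean over control genes drawn (seeded, 50 per set
gene) from the same of 25 mean-expression bins, which removes the
depth-driven component of the raw mean. The ribosomal-protein score is the
same construction over the `Rps*`/`Rpl*` genes. The gene-pair
co-expression score for a matched cell-type pair is the per-gene product
of the two mean normalized profiles — genes high in *both* types rank
first, and the score is symmetric.

## CCAT and homology weighting

CCAT approximates network (signaling) entropy by the Pearson correlation
between a cell's expression vector and the connectome degree vector over
shared genes. It inherits Pearson's invariance to positive affine
transforms per cell; cells with zero expression variance over the shared
genes are undefined and flagged rather than scored. Degrees are used raw
by default with a `log_degree` option; the connectome is any undirected
edge-list TSV (self-loops and duplicate edges are dropped; isolated genes
have no degree).

For cross-species use, the homology pair table (one-to-one through
many-to-many) becomes a binary incidence matrix normalized **per human
gene**: each human gene's incoming weights sum to 1, so its projected
value is the equal-weight average of its source homologs. The quoted
normalization convention is ambiguous between rows and columns; we chose
per-human-gene (column) normalization because the projection target is the
human gene space and an unnormalized many-to-one column would double-count
expression. A one-to-many source gene legitimately contributes with weight
1 to each of its human genes. The tests verify that projection through a
one-to-one table leaves CCAT identical to the unprojected score.

## Pseudo-cells and neighbor-voting AUROC

Pseudo-cells stabilize sparse profiles: within each cluster, cells are
shuffled under a seed and partitioned into disjoint groups of exactly 100;
counts are summed per group. Remainder cells are dropped (configurable to
pool into the last group) and no cell is used twice — aggregating counts
first and normalizing downstream keeps the pseudo-cell on the same scale
as a deep single cell.

Cross-dataset matching is rank-based end to end: Spearman correlations
between all sample pairs over a shared HVG set; each target sample's
correlation vector rank-standardized to (0, 1]; votes for a (type, sample)
pair are the mean standardized correlation to the source samples of that
type; and the AUROC is computed by the Mann–Whitney rank formula with
average ranks, so all-tied votes give exactly 0.5. The consequence —
invariance to any monotone transform of expression — is asserted in the
tests. Cell-type pairs with AUROC strictly greater than 0.9 are called
consistent. Types with fewer than two samples are excluded because a
single sample cannot support a rank statistic.

## Time-course optimal transport

Couplings between adjacent timepoints minimize

⟨C, π⟩ + λ₁·KL(π𝟙 ‖ p) + λ₂·KL(πᵀ𝟙 ‖ q) − ε·H(π)

with λ₁ = 1, λ₂ = 50, ε = 0.05 and a single growth iteration (growth
estimates, default 1, are used as-is and never re-fit). The solver is a
log-domain stabilized scaling iteration with the unbalanced exponent
λ/(λ+ε), tolerance 1e-8 on the dual change, at most 5000 iterations;
non-convergence returns the current coupling with a flag rather than
failing. The cost is squared Euclidean distance between cells in a common
30-PC embedding of the ln-normalized HVG matrix, normalized by its median
— the embedding is a package choice (the source material computes maps "in
gene-expression space" without fixing the cost), and raw gene space is
available by passing the identity embedding. With λ₂ = 50 the target
marginal is matched closely but not exactly: across our simulations the
column sums deviate from uniform by 0.2–0.4% on average (worst single
column ≈ 2%), the total mass stays within 1% of 1, and both are asserted
at those magnitudes.

Long-range couplings compose as Markov products of the *row-normalized*
adjacent couplings, rescaled to unit mass. Pull-back row-normalizes each
stored coupling before applying it and renormalizes the result at each
step; because renormalization commutes with the linear maps, pulling back
through a composed coupling equals sequential pull-back exactly (the tests
require 1e-10). Trajectory membership applies the strict 0.00025 threshold
to the normalized ancestor distribution; divergence between two
trajectories is 0.5 × Σ|p − q| (half the total-variation distance, a
metric bounded by 1); gene trends are distribution-weighted expression
means; and driver ranking is the per-gene Pearson correlation with a fate
probability vector, with zero-variance genes ranked last as undefined.
Fate probabilities may come from this package's own pull-forward
(row-stochastic composition summed over terminal sets) or any external
per-cell probability file.

## The synthetic-data generator

The generator's defaults are the study conditions the analyses assume, at
desk scale:

* **Reads** — 3×24 + 96 whitelist sequences (rejection-sampled to pairwise
  Hamming distance ≥ 3; a 6-bp alphabet cannot support hundreds of
  distance-3 codes, so segment sizes are modest by construction), 28-bp
  prefixes on read 1, per-base substitution errors at 0.1% by default,
  qualities consistent with error status (Phred 37 clean, 14 on error
  bases, optional planted Phred-2 bases to exercise the quality gate).
* **Alignments** — a 2.2-Mb toy genome with 30 annotated TSSs; "good"
  cells (2500 fragments) place insertion sites N(0, 15 bp) around TSSs
  while "background" cells (600 fragments) insert uniformly, so good cells
  clear both QC thresholds and background cells fail both; 10% planted PCR
  duplicates; 2% of fragments on chrM to exercise the exclusion filter.
  Raw SAM coordinates are emitted pre-shift so the +4/−5 correction
  recovers the planted fragments exactly.
* **Time course** — four timepoints × 500 cells, two branches separating
  at the second timepoint, negative-binomial counts (dispersion 0.1)
  around log-mean programs drifting 0.8 per step along 40 branch genes per
  branch; 10 designated driver genes per branch; 25 hub genes wired into a
  toy connectome (40 edges each vs 1 for the rest); a metastable
  population (30% of branch-point cells) over-expressing the hub genes by
  1.2 log units; cell-cycle and RP modules pulsing at the branch point and
  one step later, echoing the proliferation phases the study observes.

Sample sizes were chosen so the whole suite runs in about two minutes:
500 cells per timepoint is the smallest scale at which the two branches
are unambiguous to transport, and 100k reads give the demultiplexer's
accuracy estimate three significant digits.

What passing these tests shows — and does not. The generator produces
substitution errors only (no indels or quality ramps), no doublets or
ambient RNA, no batch structure, and branch programs that drift smoothly
with equal cell numbers per branch. Success here demonstrates the
*correctness* of the implementations (shifts, dedup keys, marginals,
rank statistics, normalizations) and their behaviour under the planted
signal structure; it does not certify performance on real data, where
error processes, depth variation and unbalanced populations are harsher.

## Numerical and degenerate-input conventions

Minimum pairwise Hamming distance of a singleton set is ∞ (no constraint).
Zero-fragment cells score TSS enrichment 0 with a flag. Zero-variance
cells and genes are flagged/`NA`, never silently 0. HVG ties break by gene
identifier; pseudo-cell grouping, control-gene draws and all simulators
consume explicit seeds and restore the session RNG state. The Sinkhorn
solver works entirely in the log domain, so ε = 0.05 with median-normalized
costs (entries ~20/ε) is stable. Composition renormalizes at unit mass to
avoid underflow over long chains.

## Known limitations

The TSS-enrichment implementation aggregates per cell over all sites at
desk scale (dense tabulation); for atlas-scale fragment files a streaming
implementation would be needed. The neighbor-voting implementation
computes the dense cross-correlation matrix, quadratic in sample count —
intended for pseudo-cells and moderate datasets. Growth estimation from
proliferation/apoptosis scores is provided as a hook (`growth` argument)
but defaults to 1, matching the single-growth-iteration setting; no
iterative growth re-estimation is implemented.
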