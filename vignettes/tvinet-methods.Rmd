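---
title: "Methods: repertoire variation, gene screening and module discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire variation, gene screening and module discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvinet)
```

# The problem

During gastric carcinogenesis the T cells infiltrating a lesion are expected
to diverge, clone by clone, from those of the surrounding mucosa. This
package quantifies that divergence from paired clonotype tables, relates it
to the local gene-expression phenotype, and extracts a tightly
interconnected gene module whose expression stratifies survival. Everything
downstream of clonotype assignment is in scope; read processing, V(D)J
alignment, microarray normalization and public-database retrieval are not.

# Clone identity

A clonotype table does not itself say what a "clone" is. The default key is
the CDR3 **nucleotide** sequence plus V and J gene (mode `nt_vj`):
nucleotide-level identity is the conservative choice for aligner output
that distinguishes segments, since distinct rearrangements converging on
one amino-acid CDR3 remain distinct. `nt_only` and `aa_vj` modes are
provided; allele suffixes (`*01`) are stripped by default because upstream
tools disagree about emitting them. All overlap statistics inherit this
choice, so a repertoire records its key mode and refuses comparison across
modes.

Ordering is total and deterministic — frequency descending, key ascending —
so TOP-N membership never depends on input order. Frequency columns are
trusted only when they sum to 1 ± 1e-3 (tolerating rounded published
tables, renormalized quietly); otherwise they are recomputed from counts,
or rejected when recomputation is disabled.

# Overlap statistics and the variation index

For a matched pair, with the lesion as reference:

* **overlap ratio** = shared unique clones / lesion unique clones;
* **cumulative frequency of common clones** = summed lesion-side
  frequencies of shared clones;
* **TOP-N overlap**: the fraction of the lesion's N most expanded clones
  found anywhere in the adjacent repertoire.

The repertoire variation index combines mass and rank agreement:

$$\mathrm{TVI} = 2 - F\,(1 + C), \qquad F \in [0,1],\; C \in [-1,1],$$

so $\mathrm{TVI}\in[0,2]$, with 0 for identical and 2 for disjoint
repertoires.

Two conventions needed fixing:

* **F is renormalized within the TOP100** (shared TOP100 lesion mass /
  total TOP100 lesion mass). Reported stage-wise values of this quantity
  (≈ 90–97%) exceed the TOP100's whole-repertoire coverage (≈ 50%), so only
  the renormalized reading is numerically consistent; the
  whole-repertoire-denominator variant stays available via
  `renormalize = FALSE`.
* **"Top common clones"** is membership-based: every shared clone in the
  TOP100 of *either* sample enters C, however many that is. C uses
  average-rank Spearman correlation on raw frequencies (any strictly
  monotone transform gives the same value).

Degenerate pairs: with fewer than 3 top common clones C is undefined. If
F = 0 the index equals 2 regardless of C (the short-circuit limit);
otherwise the TVI is reported missing with a warning rather than invented.

# The expression screen

Per-gene average-rank Spearman correlation against per-sample TVI, with a
two-sided p-value from the t approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$
(adequate at the screen's intended n ≈ 22), and Benjamini–Hochberg step-up
q-values. Genes constant across samples are dropped before testing — their
ranks are undefined — rather than assigned p = 1. Direction calls
(positive/negative/null) are made at FDR < 0.05 by default. One-sided
testing was considered and rejected: the screen's two tails feed two
distinct gene sets, which is exactly the two-sided decomposition.

# Network construction and module detection

Edges from a STRING-style table are kept under **strict** inequalities
(text mining > 200 AND combined > 400 on the 0–1000 score scale) with both
endpoints inside the gene universe (the TVI-correlated genes). A second
filter keeps an edge only when its genes' expression profiles reach
|Spearman ρ| ≥ 0.5 — the source convention names the test but no threshold,
so the value is explicit, config-exposed, and recorded on each edge.

On the largest connected component (lexicographic tie-break for
determinism):

* **Scale-free check.** R² of the least-squares fit of log₁₀ degree
  frequency on log₁₀ degree, the conventional scale-free topology index;
  "power" is not defined in the source, and this index is the standard
  reading in co-expression network practice. The slope's negation is
  reported as the exponent. A two-point fit (e.g. a star graph) has R² = 1
  by construction and is flagged `degenerate`.
* **Hubs.** Nodes at or above the 95th degree percentile (type-7 quantile),
  ties included — so the hub count may differ from ⌈0.05 n⌉, as observed
  hub counts do — plus all first neighbours, as an induced subgraph.
* **CPM communities.** A community is the union of k-cliques connected
  through (k−1)-node overlaps. Implementation: Bron–Kerbosch maximal
  cliques of size ≥ k (via igraph), joined when sharing ≥ k−1 nodes, then
  connected components — equivalent to percolating the individual k-cliques
  but far cheaper. The test suite keeps an independent brute-force oracle
  that enumerates *all* k-cliques and joins exact (k−1)-overlaps; the two
  agree on 100 seeded random graphs up to 12 nodes.
* **Module selection.** k is raised from 3 until no community survives; the
  selected module is the largest community at the last surviving k
  ("highest stringency"), ties broken lexicographically. Nestedness of CPM
  communities across k guarantees the incremental search is exact.

# Survival stratification

Hierarchical clustering (Euclidean distance on per-gene z-scored profiles,
average linkage — both unspecified in the source and therefore
config-exposed, with Ward and correlation-distance options) cut at two
groups; group 0 is defined as the lower-mean-expression group so labels are
reproducible. The Kaplan–Meier estimator and the two-group log-rank test
are implemented from first principles (events precede censorings at tied
times — stated because the convention matters and sources are often
silent); both are validated against the `survival` package and against
hand-computed worked examples.

# The synthetic world

The generators state one world and stay there:

* **Clone abundances**: Zipf with exponent 1.01 over 20,000 clones and
  200,000 reads per sample. Calibrated once, before any acceptance test
  existed, so that TOP100 coverage lands at ≈ 0.51, inside the observed
  46–54% band; not revisited since.
* **Pairing**: a frequency-weighted subset of adjacent clones is copied
  into the lesion with multiplicative log-normal rank noise; remaining
  lesion clones are fresh tail clones under the same noise, so strong noise
  lets lesion-specific clones expand into the TOP100 — reproducing the
  qualitative signature of progression (shared top clones losing rank,
  private clones amplifying).
* **Stage presets**: shared fractions 0.1511 / 0.1074 / 0.0902 are the
  observed stage-wise overlap ratios taken as given; rank noise 0.35 / 0.8
  / 1.3 rises across stages. Mean TVI then increases LGIN → HGIN → EGC as a
  property of the world, not a fitted number.
* **Expression**: planted genes are ±1 × standardized TVI rank plus
  N(0, 0.5) noise on a log-intensity-like scale (22 samples by default),
  an operating point where planted genes carry |ρ| ≈ 0.9 and survive FDR
  0.05 with ≥ 90% power; null genes are pure noise, so realized FDR under
  the global null is checked honestly.
* **PPI**: the module is an explicit chain of overlapping k-cliques
  (consecutive cliques share k−1 nodes) over 11 genes at k = 5; background
  edges are Erdős–Rényi at 0.05 *outside* the module — a chance chord
  inside the chain would silently raise its percolation stringency above k,
  which is why the generator forbids it. Sub-threshold decoy edges exercise
  the score filter.
* **Survival**: exponential event times (baseline hazard 0.1, hazard ratio
  3, exponential censoring at 0.02), two groups of 50.

What a green test does **not** establish: real repertoires are not Zipf
with a single exponent (the generator has no sequencing-error clones, no
V/J usage bias, no saturation effects); real expression is not Gaussian
around a monotone TVI trend; a real PPI network is not an Erdős–Rényi
background around one clean clique chain; and real hazards are not
proportional exponentials. The generators exist to verify the *statistical
machinery* at a realistic operating point, not to claim biological realism.

One stated limit is approximate by design: with full sharing and zero rank
noise the lesion and adjacent draw separate multinomial read samples, so
the identity limit TVI = 0 holds in expectation but not exactly per draw;
the exact identity case is asserted on literally identical clone tables,
and the generator limit as TVI < 0.1.

# Numerical choices

* Shannon diversity in nats by default (base config-exposed); the
  normalized variant (÷ ln richness) is an explicit extra.
* Frequency sum tolerance 1e-6 after validation; 1e-3 trust band for
  supplied frequency columns.
* Spearman p-values floor at the smallest positive double rather than 0 so
  BH input stays in (0, 1].
* TVI values outside [0, 2] by more than 1e-9 are an error, never clamped
  silently.
* All pipeline randomness derives from one seed through fixed per-stage
  offsets; stages communicate only via files so any stage can be re-run
  and audited.

# Known limitations

* The overlap ratio's denominator convention for TOP-N (out of
  min(N, richness)) is one of two defensible readings; the other is a
  one-line change.
* CPM by maximal-clique enumeration is exponential in the worst case; it is
  intended for hub-network scale (tens of nodes), with the brute-force
  oracle reserved for even smaller test graphs.
* The log-rank implementation covers two groups only; stratified or
  trend variants are out of scope.
* Screen p-values use the t approximation only; it is slightly
  anticonservative below n ≈ 10, and an exact permutation option was
  deliberately not built — the screen's intended regime (n ≈ 22) does not
  need it, and a partial implementation would invite misuse at the very
  sample sizes where its own Monte-Carlo error dominates.
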