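---
title: "Comparing native and organoid retinal development: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing native and organoid retinal development: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Retinal organoids grown from induced pluripotent stem cells broadly
recapitulate native retinogenesis, but "broadly" needs numbers. Given
droplet scRNA-seq of the two systems at four matched developmental stages
(I–IV), `retcomp` quantifies how they differ along several complementary
axes:

* **Trajectory width** — are developmental paths through expression space
  tighter in the native retina than in the organoid?
* **Within-stage cell-type diversity** — does a fixed developmental stage
  host a broader mix of cell types in the organoid (relaxed temporal
  control)?
* **Cell-type-specifying genes and condition contrasts** — which genes
  define each of the 13 canonical retinal cell types, and which of them the
  culture conditions perturb?
* **Pathway enrichment with found-entity colouring** — which gene sets are
  over-represented in those lists, and which enrichments are driven by the
  same underlying genes?
* **Profile correlation** — per gene, does the organoid reproduce the
  native expression profile across cell types?

Every statistic runs on a `cell_table`: a cells × genes UMI count matrix
with per-cell condition (`native` / `organoid`), stage (`I`–`IV`), cluster
id, optional cell-type label, and an optional 2D embedding. Clustering and
embedding are consumed as inputs — the package deliberately does not fit
them, so any upstream toolchain can feed it. Expression enters every
downstream statistic as *fraction of UMI* (each cell's counts divided by
its total), with cells of zero total count flagged and excluded.

## Trajectory width

For a cell on a 2D embedding, the mean Euclidean distance
$\sqrt{(x_1-x_2)^2 + (y_1-y_2)^2}$ to its $n$ nearest neighbours (self
excluded) measures the local point density; averaged over sampled cells and
swept over $n = 1..50$ it traces a curve whose height reflects how
dispersed — how "wide" — the condition's developmental paths run.

Protocol (per down-sampling replicate, default 5):

1. within each stage, the more populated condition is down-sampled without
   replacement to the size of the less populated one, so abundance
   differences cannot masquerade as dispersion differences;
2. 500 cells are sampled per condition from the balanced pool;
3. each sampled cell's neighbours are searched within the balanced pool of
   *its own* condition — the statistic measures each system's own path
   width, not cross-condition separation;
4. the aggregate curve is the mean across replicates, the envelope the
   pointwise min/max.

The curve is non-decreasing in $n$ by construction (a mean over the $n$
smallest distances), and dilating all coordinates by a factor scales it
exactly by that factor — both are tested. When a pool is smaller than
$n_{max}+1$, $n_{max}$ is capped at pool size − 1 with a logged warning
rather than an error, which keeps small pilot datasets usable.

## Within-stage diversity

Within a condition × stage block (after the same equalization), two
distinct cells are drawn and checked for sharing a cell-type label; the
fraction of matching pairs over 1000 draws is a concentration statistic
akin to 1 − entropy. Its large-sample expectation is the unbiased Simpson
index $\sum_i n_i(n_i-1)/(N(N-1))$ of the block composition, which the
tests verify on fixed compositions. Down-sampling is repeated 100 times
with pairs redrawn each replicate, giving a distribution of samples per
condition × stage. Lower values mean more diversity; relaxed temporal
control in organoids shows up as organoid values below native ones.

Pairs are distinct within a pair but drawn with replacement across pairs.
Both resampling statistics canonicalize their blocks before the seeded
draw (labels sorted; pool cells ordered by coordinates), so results are
invariant to the storage order of cells — only the data, never the row
order, can change a number.

## Annotation

The paper trail for cluster annotation in this field is thin, so the
package adopts the simplest reproducible rule: expression is normalized as
$\log(1 + 10^4 \cdot \text{fraction})$, z-scored per gene across cells
(zero-variance genes contribute 0, not NaN), a signature scores as the mean
z over its genes averaged within cluster, and a cluster takes the argmax
label among the 13 type signatures — unless the top score is negative or
leads the runner-up by less than 0.05, in which case it is `NI`
(not identified). Exact ties break by signature order and are logged.
Cell-cycle phases (S, G2-M) use the same scores per cell with an
argmax-if-positive rule; on noise alone that rule fires liberally, which is
why phase calls are interpreted through their planted-recovery rate rather
than their raw counts.

## Differential expression

The test is the two-sided Wilcoxon rank-sum: exact enumeration of the
rank-sum distribution when both groups have ≤ 10 cells (valid under ties),
otherwise the normal approximation with tie-corrected variance. Log fold
changes are natural logs of mean fraction-of-UMI ratios with a $10^{-9}$
pseudocount. Three analyses share this machinery:

* **cell-type-specifying genes**: each type against all other cells, kept
  at ln-fold ≥ 0.25 and p ≤ 0.001 (the thresholds are configurable; the
  0.25 threshold is interpreted on the natural-log scale);
* **condition contrasts**: native vs organoid within each type, split by
  direction, BH-adjusted within each (type, direction) family, kept at
  q ≤ 0.01 — swapping condition labels provably swaps the two output lists;
* **TF specificity**: among specifying genes in a user-supplied TF list,
  the ratio of the top type mean to the best remaining type mean, flagged
  at ≥ 1.5.

Bootstrap percentile intervals (1000 resamples, 99% level) accompany mean
expression values; their coverage is verified by simulation at ±2%.

## Enrichment and the found-entity palette

Gene-set enrichment is a local exact hypergeometric upper tail against a
universe of all detected genes, with the overlapping genes — the *found
entities* — recorded per result, since they and not the set name define
what an enrichment means. Results are BH-adjusted within a collection and
kept at p ≤ 0.01 by default.

Because different pathways are often enriched through the same genes, each
result is encoded as a binary presence/absence row over the union of found
entities; the matrix is reduced to its first 20 principal components
(SVD, deterministic sign convention) and embedded in 3D with a seeded
exact t-SNE written for this package. Duplicate rows are collapsed before
the embedding and re-expanded afterwards, so identical found-entity sets
receive bit-identical coordinates — and therefore identical colours — by
construction rather than by convergence. Each 3D axis is min-max scaled to
0–255 and rounded half-up into an `#RRGGBB` colour. The embedding ships a
diagnostic (fraction of 5 PC-space nearest neighbours preserved in 3D);
the contract is colour similarity tracking found-entity overlap, which the
tests check via silhouette and a Spearman correlation between colour
distance and Jaccard distance, not any particular embedding geometry.
t-SNE perplexity defaults to 30, capped at (rows − 1)/3; with three or
fewer distinct rows the leading PCs are used directly, padded to 3D.

## Profile correlation

For a gene panel (disease genes, markers), the per-type mean
fraction-of-UMI profile across the 13 types is computed in each dataset
and correlated per gene (Pearson by default — the profiles are 13-point
vectors and the summary is a median r; Spearman is a flag). Genes with a
flat profile in either dataset are excluded and counted rather than
assigned r = 0. Matrices must share at least 3 type columns; correlation
uses common columns only. Cross-species comparisons are supported through
a user-supplied ortholog table upstream — no ortholog database is built
in.

## The synthetic generator

The generator exists so every statistic can be validated against known
ground truth. It emulates the *statistical structure* the analyses assume:

* a 2D branching trajectory tree of 13 segments, one per cell type, laid
  out so consecutive stages hand over their dominant types (RGC emerging
  in stages I–II; HC, AC, PRP in II–III; C, R, BP, MC in III–IV), with a
  root neuroepithelium and the known branch order (NE → RPE / ERPC,
  ERPC → NRPC → RGC/HC/AC, LRPC → PRP → C/R, LRPC → BP/MC);
* cells placed uniformly in pseudotime along branches overlapping their
  stage window, jittered isotropically — native sigma 0.3, organoid 0.6
  (embedding units), the relaxed-spatial-control effect;
* organoid cells drawing their position from an adjacent stage window with
  probability 0.15 (boundary stages use their single neighbour), the
  relaxed-temporal-control effect;
* an organoid-only abundance multiplier (default: PRP × 1.5 at stages
  II–III) mimicking premature photoreceptor-precursor dominance;
* negative-binomial counts (dispersion 0.5) over log-normal baseline gene
  weights and library sizes (median 5000 UMI), with 10 planted markers per
  type boosted e^1.5 in their own type, 2 of which per type carry
  organoid-only perturbations of e^±1.0, plus 10 S and 10 G2-M phase
  markers boosted in cycling progenitors (30% of ERPC/LRPC/NRPC cells).

Counts are *not* renormalized to an exact library total, so planted folds
are exact in expectation and recovery tests compare against the configured
multiplier directly. Effect sizes were chosen once to make recovery
decisive — 500 cells per condition × stage resolve an e^1.5 marker boost
essentially perfectly — not to match any published effect magnitude, for
which the real datasets would be required. What passing tests show is that
the statistics recover what was planted under their own assumptions; they
do not show that real organoids differ by these magnitudes, and the
generator deliberately omits transcriptome-wide co-expression, doublets,
ambient RNA and spliced/unspliced layers.

The embedding is generated directly rather than simulated-then-reduced:
the dispersion statistics operate on the embedding, and generating it
keeps their ground truth exact.

All randomness flows from one seed fanned out to named per-stage streams,
so stages can re-run independently and a pipeline run is reproducible
bit-for-bit; the seed is recorded in every output.

## Numerical choices and degenerate inputs

* Zero-count cells are retained in the object but excluded from every
  statistic (undefined fractions otherwise).
* Zero-variance genes z-score to 0; zero-variance profiles are excluded
  from correlation; a zero-variance found-entity matrix is an error.
* Rounding of reported percentages is half-up (one decimal by default,
  integer on request), matching how such proportions are conventionally
  printed.
* The hypergeometric tail is computed by `phyper` (exact, stable in log
  space); BH by `p.adjust`; the binomial tail by `pbinom`. The rank-sum
  test is implemented in-package because the stock test cannot enumerate
  exactly under ties; it is cross-checked against the stock implementation
  on the tie-free path and against full enumeration on small groups.
* Typical problem sizes: the default synthetic dataset is 4000 cells ×
  600 genes, which runs the full pipeline in well under a minute; the
  statistics scale linearly in genes and — via the per-condition pools —
  quadratically in pooled cells for the width curves.

## Known limitations

* The width statistic inherits every distortion of the 2D embedding it is
  given; it quantifies dispersion *on that map*, not in expression space.
* The diversity statistic depends on the granularity of the cell-type
  labels; finer typing mechanically lowers same-type pair fractions.
* The argmax annotation rule has no reject option beyond the margin/NI
  rule and does not model doublets or gradients.
* Enrichment universes matter: the package refuses to default the universe
  for list-overlap tests, because the choice changes the answer
  qualitatively.
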