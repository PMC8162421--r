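---
title: "Methods: comparative single-cell atlas analysis with polypatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative single-cell atlas analysis with polypatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

polypatlas implements the comparative analysis layer used for whole-organism
single-cell RNA-seq atlases of cnidarians (a coral host together with its
algal symbiont is the motivating system): expression footprints over
metacells, cell-type dendrograms with jackknife support, cross-species
cell-type homology mapping, gene-age (phylostratigraphy) analysis,
count-based differential expression, host--symbiont co-profiling, and
3' gene-model extension. This vignette explains each model, the tunable
parameters, the synthetic-data generator used for validation, and the
numerical and design choices that were genuinely open.

## Expression footprints

The atomic unit of quantification is the *metacell*: a small,
transcriptionally homogeneous group of cells, consumed here as an input
assignment (the graph partitioning that produces metacells is a separate,
published procedure and is deliberately out of scope). Expression of gene
$i$ in group $g$ is summarized as a regularized geometric mean of
depth-scaled per-cell fractions,

$$\mathrm{geo}_{ig} = \exp\Big(\tfrac{1}{|g|}\sum_{c\in g}\log(f_{ic} + \varepsilon)\Big) - \varepsilon,
\qquad
\mathrm{FC}_{ig} = \frac{\mathrm{geo}_{ig}+\varepsilon}{\max\big(\mathrm{median}_h(\mathrm{geo}_{ih}+\varepsilon),\ \varepsilon\big)},$$

where $f_{ic}$ is the cell fraction scaled to a common depth. The
fold-change (FC) matrix is the currency of every downstream module. Three
details of this formula are not uniquely determined by its verbal
description, so the package fixes them explicitly and records them in the
output object: the common depth is the median cell total of the dataset;
$\varepsilon$ defaults to 0.1 on the depth-scaled fraction level; and the
median floor equals $\varepsilon$. The geometric mean damps bursty
outliers relative to an arithmetic mean, and the median normalization
makes FC values comparable across genes; its defining invariant — the
median of each gene's FC across groups is 1 whenever the
pre-normalization median clears the floor — is property-tested on random
matrices.

Cell-level QC retains cells with `min_umi <= total <= max_umi`
(defaults 100 and 8,000 UMIs; the lower bound is typically raised to
150--200 for polyp or larval libraries). Bounds are inclusive: the verbal
rule "< 100 is removed" leaves the boundary ambiguous, and we fix
boundary-keeping semantics.

Feature-gene selection combines strict count filters (detected with > 1
UMI in at least 3 cells; total strictly above 30 UMIs), an exclusion list
(ribosomal proteins, histones), and a *normalized size correlation*
filter. The exact size-correlation statistic of the original metacell
machinery is internal to that software, so the package defines its own,
documented stand-in: the Pearson correlation between a gene's raw
per-cell counts and the per-cell totals, centered by the mean correlation
of count-matched *size-proportional* null genes (multinomial draws with
probabilities proportional to cell totals and the same gene total). A
gene whose expression merely tracks cell size scores near zero; a bursty
or cell-type-restricted gene scores clearly negative. Genes with a
statistic below `size_corr_thr` (default -0.05) are kept. A population in
which every gene is size-proportional therefore returns an empty list —
this is exactly the behaviour exploited by the symbiont heterogeneity
screen below, where an empty result is a biological verdict, not a
failure. A user-supplied marker list can always replace this heuristic to
reproduce any external selection exactly.

Metacell QC is semi-supervised: a metacell passes when it expresses at
least `min_markers` marker genes (expressed means FC > 1; the source
procedure does not define it, so this is a documented choice) *and* its
mean cell total reaches the mode of the per-cell UMI distribution
(estimated as the midpoint of the tallest Freedman--Diaconis histogram
bin, overridable by an explicit threshold). Three exceptions rescue
otherwise-failing metacells: more than 2 transcription factors at
FC > 2; a symbiont signal above 10,000 UMIs; or any rescue-list marker
(e.g. cnidocyte markers) at FC > 1.5. Whether the UMI-peak rule refers to
metacell mean or median totals is not specified anywhere; we use the
mean.

## Cell-type trees

Cell types (groups of metacells) are compared by Pearson correlation of
their log2 FC profiles over variably expressed genes (max FC > 1.8 by
default). Because FC is ratio-scaled, correlating on log2 values is the
natural choice; linear-FC correlation is available behind a flag. The
co-occurrence procedure repeats, `n_iter` times (1,000 by default):
jackknife-sample 75% of the variable genes without replacement, cluster
the cell types by average linkage on $d = 1 - r$, cut the dendrogram at
the iteration's height $h$ (half the iterations at $h = 0.75$, half at
$h = 0.95$ by default), and count each within-cluster pair. The scale of
$h$ was genuinely open; we place it on the cophenetic height of
$1 - r$, so $h = 0.75$ merges clusters down to correlation 0.25.

The final tree is average-linkage (UPGMA) clustering of
$1 - \mathrm{counts}/n_\mathrm{iter}$, agglomerated in-package with
Lance--Williams updates so that ties in the minimum inter-cluster
distance can be broken deterministically toward the lexicographically
smallest merged tip set. (A library clusterer leaves tie order
unspecified, which makes equal-count matrices irreproducible; the
in-package agglomerator is oracle-tested against a naive pair-merge
implementation on hundreds of random matrices.) Node support repeats the
jackknife clustering and reports the percentage of replicate trees
containing each node's exact tip set; clade identity is rooted (the
dendrogram is rooted, so bipartition semantics would be artificial), and
root and tips are 100 by convention. Nodes below 10% support are
collapsed to polytomies; collapsing preserves every surviving clade's
height and support.

*Node-supporting genes* characterize a node: genes with FC > `fg_thr`
(default 1.7) in (nearly) all descendant tips and FC < `bg_thr` (default
1.8) in (nearly) all other tips. The *leakiness* parameters give the
tolerated fraction of violating tips on each side. Two variant modes
restrict the background to the sister clade, or swap foreground and
background ("features out"). Monotonicity (growing leak_bg can only grow
the gene set; raising fg_thr can only shrink it) is property-tested.

## Cross-species mapping

Two species' cell-type footprints are joined over an ortholog pair table.
One-to-many orthology is handled by duplicating a gene's profile once per
*expressed* counterpart (max FC above `expressed_floor`, default 1 — the
source rule says "expressed" without a threshold), up to `max_copies`
(default 3); genes with more expressed counterparts are dropped. A pair
whose counterpart is unexpressed is kept only when the gene has no
expressed counterpart at all, so strictly one-to-one tables pass through
row-for-row.

The joint matrix is quantile normalized (each column's values replaced by
the mean of order statistics at matching ranks; ties receive the mean
over their rank span — dialects differ here, so the tie policy is pinned
and cross-checked against an independent implementation in the tests).
Each cell-type column is then treated as a probability distribution
(pseudocount `pseudo` as a fraction of column mass, default 1e-4, added
before renormalization) and compared by Kullback--Leibler divergence in
bits. The divergence direction is not determined by the problem; since
cell-type links are undirected, the default is the symmetrized mean of
both directions, with directed divergence behind a flag. Links are the
lowest-divergence 2% of all cross-species pairs (the 0.98 similarity
quantile, interpolated type-7 cutoff, ties at the cutoff included),
computed per species pair by default with a global option.

Putative homologous cell-type groups are tested by a paired two-sided
Wilcoxon signed-rank test between each shared ortholog's in-group and
out-group mean expression (shared = FC > 1.3 in every group member);
p-values are exact for 25 or fewer untied differences, otherwise the
normal approximation with continuity correction, and BH-adjusted across
all groups queried in one call. For multi-species comparisons,
`one_to_one_joint()` combines broad cell types across any number of
species over orthogroups that are strictly single-copy in all of them.

## Gene ages

Given an orthogroup-by-species presence matrix and a rooted species tree
with named nodes on the root-to-focal path (the phylostrata), strict
Dollo parsimony assigns each focal gene the most recent common ancestor
of the focal species and all species sharing its orthogroup: a single
gain with unlimited losses. Genes with no orthogroup — and orthogroups
private to the focal species — receive the youngest stratum (the
treatment of orphan genes is unstated in comparable pipelines; the count
assigned this way is logged). The implementation is verified against an
exhaustive single-gain oracle on all 256 presence patterns of an
8-species tree, and adding a species to a presence set can never make an
age younger. Age enrichment per (gene set, stratum) uses a two-sided
Fisher exact test with BH adjustment across all cells; odds ratios are
sample ORs with a Haldane +0.5 correction when a cell is zero. A
paralog-control filter (`drop_inparalogs()`) removes genes whose
orthogroup contains multiple focal genes.

## Differential expression and term enrichment

Between two cell groups, each gene is tested on the pooled-UMI 2x2 table
[gene UMIs in A, other UMIs in A; gene UMIs in B, other UMIs in B] with a
two-sided Fisher exact test (method of small p-values — summing
hypergeometric outcomes no more probable than the observed one; the
doubling dialect differs and is not used), BH-adjusted across genes, with
significance at adjusted p below 1e-5. The contingency construction is
not uniquely determined by its verbal description; pooled UMIs are the
standard for UMI-based metacell comparisons, and a cells-expressing
construction is available behind a flag. The displayed log2 enrichment is
regularized with $\rho = 1$; p-values always use raw counts. The p-value
routine is vectorized on `stats::dhyper` and is checked against both
direct enumeration (all tables with margins up to 30) and
`stats::fisher.test`. Term enrichment is the generic one-sided Fisher
test against a gene-to-term map with BH adjustment across terms; its
type-I calibration is simulation-tested with large margins (background
50,000; set 5,000; term 10,000) chosen so the hypergeometric null is
near-continuous and the nominal 0.05 level is meaningful for a discrete
test.

## Host--symbiont co-profiling

Dual matrices carry one organism label per gene (reads mapped jointly to
both genomes), mirroring a single joint quantification rather than two
files; `split_dual()` partitions them with exact conservation of per-cell
totals. Symbiont *occupancy* per metacell is the fraction of cells whose
symbiont UMI total strictly exceeds 100 (the threshold is a parameter).
Aggregate-versus-bulk comparison sums single-cell counts per gene,
quantile-normalizes the aggregate against the bulk vector (two-column
quantile normalization, making the comparison scale-free), and flags
genes with |log2 FC| > 2. The heterogeneity screen runs the host's
feature-gene selection on the symbiont matrix; an empty result is the
"transcriptionally homogeneous" verdict.

## 3' gene-model extension

3'-biased protocols place reads downstream of under-annotated gene ends.
Given stranded gene models and signal intervals, each gene is extended to
the far edge of the nearest same-strand downstream interval whose gap is
at most 2 kb and which does not overlap any other same-strand gene (an
any-strand blocking option exists; whether "downstream gene" means same
strand only was left open and same-strand is the default, since the
signal is stranded). Coordinates are 1-based closed throughout (the GFF3
convention; gap = start2 - end1 - 1, so a 2,001 bp gap fails a 2,000 bp
limit), and "distance" is the gap between the annotated 3' end and the
interval's near edge, zero when they abut or overlap. Remaining
intervals longer than 100 bp that overlap no gene become novel models
after transitive fusion of intervals within 4.5 kb (single-linkage over
the gap graph; pairwise-only fusion would be order-dependent). Extension
is idempotent and can never create same-strand overlap with the
downstream gene — both are tested on generated toy genomes covering
every rule branch.

## The synthetic-data generator

No generative model of real atlas data is implied by the procedures
above, so all simulator choices are explicit stand-ins:

* **Counts** are multinomial given a log-normal library size (median
  1,000 UMIs, log-sd 0.4 by default — a realistic MARS-seq depth). This
  matches UMI sampling semantics and gives exact expectations (under a
  flat program every gene's expected count is libsize/n_genes, checked
  within 3 standard errors over 10,000 cells).
* **Cell types** are planted expression programs: a uniform baseline with
  `markers_per_type` private markers (default 10) multiplied by
  `program_fc` (default 10), renormalized. Types grouped into blocks
  share additional block markers, which is what makes a planted
  *hierarchy* recoverable rather than a flat partition.
* **Metacells** are random splits of each planted type (at least two per
  type), because metacell partitioning itself is consumed as input.
* **Orthology** plants a single-origin (Dollo-consistent) history per
  gene: an origin node sampled on the root-to-focal path, presence equal
  to the origin clade minus independent losses (the focal species never
  loses), plus a configurable one-to-many fraction with 2--4 copies.
* **Host--symbiont** cells add, with a per-type occupancy probability, a
  log-normal symbiont load distributed uniformly across symbiont genes —
  size-proportional by construction, so the heterogeneity screen should
  return nothing unless a bimodal gene is planted.
* **Toy genomes** lay out genes and peaks so that every extension rule
  branch (both strands, in-range, beyond 2 kb, blocked by a downstream
  gene, orphan lengths straddling 100 bp, a fusable chain) occurs once
  with known truth.

All randomness flows from one integer seed (per-iteration substreams are
derived by counter, so jackknife loops are reproducible and
order-independent), and identical configurations reproduce identical
output bit for bit.

The generator deliberately omits ambient RNA, doublets, batch effects,
and sequence-level realism. Passing the recovery suites therefore shows
that the *procedures* are implemented correctly and are well-calibrated
under their own assumptions — not that they are robust to artifacts real
atlases contain.

## Validation problem sizes

The test suite runs: planted-hierarchy recovery with 6 types in 2 blocks,
500 genes, 60 cells per type, program fold-change 10, 200 jackknife
iterations, 20 seeds (both block nodes must reach 90% support);
cross-species recovery with 50 matched types in 10 blocks, 500 genes
(7 private + 12 block markers per type), 25 cells per type, 20%
one-to-many orthologs with 2--3 copies, 20 seeds (all 50 planted matches
must fall in the 0.98-quantile links — with 50 types the planted matches
are exactly the top 2% of the 2,500 cell-type pairs, which is what makes
this containment check well-posed — and every paired Wilcoxon adjusted p
must be below 0.001); Dollo oracle equivalence on all 256 presence
patterns; Fisher enumeration on all tables with margins up to 30; and
occupancy recovery at planted rates 0/0.5/1 with 500 cells per type over
20 seeds against exact binomial intervals (19 of 20 seeds must cover,
matching the intervals' nominal coverage). These sizes were chosen so
each suite completes in seconds to a few minutes on one CPU while keeping
the statistical checks sharp.

## Known limitations

* The size-correlation feature filter is a documented stand-in for an
  internal statistic of the original metacell software; selections will
  not match that software gene-for-gene. Supplying an explicit marker
  list reproduces any external selection exactly.
* Dollo ages are as good as the orthogroup inference they consume;
  homoplasy (independent gains) violates the single-gain assumption and
  biases ages old.
* The Fisher DE construction treats UMIs as independent draws; within-
  cell correlation makes the p-values anticonservative on real data, and
  the stringent 1e-5 adjusted threshold is partly a guard against this.
* Quantile normalization forces identical column distributions; genuine
  global differences in expression breadth between species are removed
  by design.
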