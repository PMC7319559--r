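---
title: "trailkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trailkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trailkit)
```

trailkit is an enrichment-analysis engine with three workflows on top of
it: chromatin-state transition enrichment, two-stage time-series
clustering, and per-cell single-cell enrichment with chi-square group
characterization. This vignette explains the statistics, the tunable
parameters and their defaults, the synthetic-data generators used for
testing, and the design decisions taken where more than one reasonable
convention exists.

## The enrichment engine

### Over-representation analysis

All workflows reduce, at the bottom, to the same question: does a gene
set of interest (a transition group, a cluster, the genes expressed in a
cell) overlap a predefined biological category more than expected by
chance? With a universe of $N$ genes, a category of $K$ genes, a test
set of $n$ genes and an overlap of $k$ genes, the over-representation
p-value is the hypergeometric tail

$$P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$

the under-representation p-value is $P(X \le k)$, and the two-sided
p-value is the doubled smaller tail capped at 1 (a simple and
conventional choice; the doubling convention matters only for the rare
borderline category). The background universe is always explicit:
`harmonize()` intersects every category with it, so $K$ counts only
genes that could have been drawn. Tests verify the tail computation
against a literal enumeration of all $\binom{N}{n}$ draws for every
design with $N \le 12$.

```{r}
u <- paste0("g", 1:10)
ora(c(u[1:3], u[5:6]), u[1:4], u)   # N=10, K=4, n=5, k=3 -> p = 11/42
```

### Running-sum set enrichment

For ranked inputs the engine provides the unweighted
Kolmogorov–Smirnov-like running sum: walking the ranking, category hits
add $1/K$ and misses subtract $1/(N-K)$; the enrichment score is the
signed maximum deviation, in $[-1, 1]$. We deliberately implement the
*unweighted* increments — the lineage of this statistic in enrichment
servers — rather than the weighted variant, which would require a
per-gene score vector the workflows here do not produce. When the
positive and the negative deviation tie exactly, the positive one wins;
this convention is arbitrary, and the antisymmetry of the score under
list reversal holds except at such ties. Significance comes from
permuting gene labels (equivalently, hit positions) with the add-one
estimator $p = (1 + \#\{|ES^*| \ge |ES|\})/(1 + B)$, which is never
zero and is reproducible because a seed is a required argument.

### Multiple testing and the 2x2 chi-square

`adjust_pvalues()` exposes Bonferroni, Holm, Benjamini–Hochberg and
Benjamini–Yekutieli through a single surface (delegating to
`stats::p.adjust`). Each workflow fixes its correction scope explicitly,
because "corrected p-values" are meaningless without one: per transition
group, per cluster, per cell, and per cell group respectively, always
across categories.

Group characterization uses Pearson's chi-square on a 2x2 table without
continuity correction,
$X^2 = N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$, with 1 df. The
continuity correction is omitted deliberately: the cell counts in the
intended use (hundreds to thousands of cells) are large enough that the
correction only costs power. Odds ratios use the Haldane correction
(0.5 added to every cell) when any cell is zero; tables with a zero
margin are reported as non-significant with $p = 1$ rather than as
errors, since a category enriched in no cell at all is an expected
outcome, not a malformed input.

## Chromatin-state workflow

Each gene receives one of four states — `active`, `poised`, `repressed`,
`no_signal` — per sample group, from the overlap of histone-mark peaks
(BED intervals, 0-based half-open throughout, 1 bp overlap sufficing)
with three gene regions: the promoter (default 2000 bp upstream to
500 bp downstream of the TSS, strand-aware, clipped at coordinate 0),
the gene body (TSS to TES) and optional enhancer intervals. The promoter
window is the common convention for promoter-proximal histone signal;
both distances are parameters.

States are decided by an ordered rule table, first match wins:

1. promoter H3K4me3 **and** promoter H3K27me3 → `poised` (the bivalent
   promoter signature);
2. promoter H3K4me3 **and** (promoter H3K27ac **or** body H3K36me3 **or**
   enhancer H3K27ac) → `active`;
3. promoter H3K4me3 alone → `active`;
4. H3K27me3 or H3K9me3 anywhere in promoter or body → `repressed`;
5. otherwise → `no_signal`.

This table encodes the canonical reading of the five marks
(H3K4me3/H3K27ac/H3K36me3 activating, H3K27me3/H3K9me3 repressive, the
bivalent combination taking precedence) and is fully replaceable by the
user — `assign_states()` accepts any list of `(state, predicate)` rules —
because reasonable variants exist, e.g. for open-chromatin or
DNA-methylation inputs. Absent enhancers never block an `active` call;
they only add evidence when supplied. Whatever the table, assignment is
total and deterministic: exactly one state per gene.

Comparing two groups yields the transition graph: genes sharing the
ordered state pair (state in group 1 → state in group 2) form one
transition group, drawn as an edge weighted by its member count. Two
conservation laws hold by construction and are asserted in tests:
per group the vertex counts sum to the number of genes, and per source
vertex the outgoing edge weights sum to the vertex count. Each
transition group with at least 2 members (smaller ones are skipped with
a warning — a one-gene ORA is vacuous) is then tested by ORA against
every category, with *all* genes that received calls as the universe.

## Time-series workflow

The input is a genes-by-timepoints matrix of normalized (assumed
log-scale) expression at three or more strictly increasing timepoints.
Processing has four steps.

**Filtering.** Genes whose range (max minus min over time) falls below
`min_range` (default 1.0, i.e. a two-fold change on log2 data) are
removed: a flat gene cannot inform a temporal clustering. Range was
chosen over variance because it is directly interpretable on log data;
the threshold is a parameter.

**Distance.** The default distance between two expression curves is the
Euclidean norm of the difference of their *gradients*,
$g_i = (v_{i+1}-v_i)/(t_{i+1}-t_i)$. This makes the distance invariant
to additive offsets — two genes with the same temporal shape but
different baseline abundance are close — which is exactly the notion of
"similar expression pattern" the workflow targets. Plain Euclidean and
$1 - r$ (Pearson) distances are available alternatives.

**Two-stage clustering.** Stage 1 cuts a complete-linkage dendrogram at
a strict height, producing small clusters whose members are pairwise
similar; clusters below `min_cluster_size` (default 5 — strict clusters
must be non-trivial for the later ORA) are discarded, and their genes
reported as unassigned rather than silently dropped. Stage 2 clusters
the *mean curves* of the surviving clusters at a larger height,
combining similar clusters into super-clusters. The two cut heights
have **no defaults**: they live on the scale of the chosen distance and
of the data, so silent defaults would be wrong more often than right.
`suggest_cut_heights()` reports the dendrogram merge heights so users
can pick cuts from the gaps; the synthetic generator computes principled
cuts from its own geometry (below). Genes are ordered lexicographically
before clustering so that equal-height merges resolve deterministically.

**Ordering and enrichment.** Super-clusters are sorted by their most
active point in time, read as the timepoint of the maximum of the
*z-scored* mean curve — z-scoring first, so that a high-amplitude
cluster does not dominate merely by amplitude; "most active" is not a
formally defined quantity and this reading is flagged as the package's
own. Ties break by larger membership, then id. ORA runs for every
cluster and super-cluster against the post-filter gene universe
(including unassigned genes, which were observed but belong to no
cluster).

## Single-cell workflow

Counts (dense table or MatrixMarket triplet) are filtered, normalized,
and tested per cell. Cell filtering removes empty-droplet proxies
(fewer than `min_genes` detected genes, default 200) and doublet
proxies (total count above median + 3 MADs of the per-cell totals);
both thresholds are parameters, and the defaults mirror common
single-cell QC practice. Normalization is log scaled-counts,
$\log(1 + c \cdot s / \mathrm{total})$ with $s = 10^4$ — per-cell
scale-invariant, so sequencing depth cancels.

Per-cell enrichment treats the set of genes *expressed* in a cell
(nonzero count by default; a top-$k$ criterion is available because
"expressed" has no canonical per-cell definition) as the ORA test set
against the full gene universe of the matrix. The background is global,
not cell-specific: the universe a cell's expressed set is drawn from is
the gene panel of the experiment, and a global background keeps
p-values comparable across cells. P-values are adjusted per cell across
categories (BH), and a cell counts as "enriched" for a category when
the adjusted p is at most `alpha` (default 0.05).

Group characterization then asks, for every annotation value (age
group, tissue, precomputed cluster label — the package consumes labels
computed by external single-cell toolchains and computes none itself)
and every category: are the group's cells enriched for this category
more or less often than all other cells? The 2x2 table (enriched / not
enriched x in group / outside) feeds the chi-square test above;
adjustment is across categories within each group; significant results
are called `predominantly_active` (odds ratio > 1) or
`predominantly_inactive` (odds ratio < 1). Note that a+b+c+d equals the
number of cells for every category — a conservation law asserted in
tests. When two groups partition the cells, a pathway active in one
group mirrors its 2x2 table in the other, producing an equal chi-square
for the depletion; rankings of "active" pathways therefore filter on
the call, not only on the p-value.

## Synthetic-data generators

Every workflow ships a deterministic generator producing inputs with
known ground truth. All randomness flows from a single seed through
named substreams (one per output), so adding an output never shifts the
others, and a fixed seed reproduces files byte for byte. The generators
write exactly the text formats the workflow readers consume.

**Epigenome.** A target state is sampled per gene and group (uniform-ish
mixture by default), and peaks are placed inside the promoter or body
exactly as the rule table requires for that state — active genes
realize their activating evidence through promoter H3K27ac or body
H3K36me3 at random, repressed genes through H3K27me3 or H3K9me3. State
recovery is therefore 100% by construction, which is the point: the
fixture tests the plumbing (regions, overlap, rule order, graph
conservation), not the biology. Genes sit 10 kb apart on one
chromosome so peaks never bleed across genes.

**Time series.** The default grid is 13 timepoints at 2 h intervals
over 24 h, the design of a typical dense stimulation time course. Each
super-group's template curve is a dominant Gaussian bump at its own
peak time (peaks evenly spaced over the time span) plus a
super-group-specific oscillation, so that super-group templates are
strongly separated in *gradient* space — separation by peak time alone
is weak there, because gradient distance saturates once bumps stop
overlapping. Sub-cluster templates are small time shifts of the
super-group template, calibrated by root finding so adjacent
sub-templates sit at gradient distance $0.5 \cdot \mathrm{amplitude}$.
Gene rows add i.i.d. Gaussian noise (default sd = 10% of the
amplitude). The generator also returns suggested cuts computed from its
geometry: the strict cut is the larger of half the sub-template
separation and 1.4 times the expected noise diameter
$2\sigma\sqrt{2(T-1)}/\overline{\Delta t}$, and the super cut is the
midpoint of the largest within-super and smallest between-super
template distance. At the default noise the planted hierarchy is
recovered exactly (adjusted Rand index 1 in the acceptance runs); at
zero noise the same formulas recover all sub-clusters. What the fixture
does *not* emulate: heteroskedastic noise, missing values, unequal
cluster sizes, or genes that belong to no temporal pattern — passing
tests say the pipeline recovers clean planted structure, not that real
time courses decompose this cleanly.

**Single cell.** Cells come in named groups; the default sizes are
2219 + 1998 + 4113 = 8330 cells in three age groups, the design of the
aging-mouse microglia atlas this workflow is aimed at. Categories are
disjoint gene blocks; each group has one planted-active category whose
genes are expressed with probability 0.9 in that group and 0.1
elsewhere, background genes at rate 0.1, and expressed counts are
1 + Poisson(1). These are idealized Bernoulli expression profiles: no
dropout structure, no depth variation, no correlated modules — so the
fixture validates the contingency pipeline and the direction of calls,
not robustness to real scRNA-seq noise. Because the background rate is
an idealized 10% of a small gene panel, the empty-droplet filter is
typically relaxed (`min_genes` well below 200) when running workflows
on this fixture.

## Numerical choices and edge cases

* Hypergeometric tails come from `phyper`; $P(X \ge k)$ uses
  `phyper(k-1, ..., lower.tail = FALSE)` to stay in the upper-tail
  branch rather than computing $1 - P$.
* Empty test sets, test sets outside the universe, categories disjoint
  from (or covering) a ranking, zero cut heights, degenerate 2x2
  margins and zero-total cells are errors with specific messages, not
  silent results; the exceptions (skipped small transition groups,
  degenerate characterization tables, categories dropped by
  harmonization) warn and continue, because they occur routinely in
  legitimate runs.
* All result tables serialize with 6 significant digits for p-values
  and fixed column order, so identical runs produce byte-identical
  files; the CLI writes a `manifest.json` recording inputs, parameters,
  seed and package version with every run.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything they
measure: ORA enumeration up to $N = 12$ (1573 designs), 1000 random
chi-square tables, 10\,000 random p-vectors for the correction
invariants, 5000 genes x 2 groups for state recovery and graph
conservation, 3 super-groups x 2 sub-clusters x 30 genes at 10% noise
for cluster recovery, and 2 groups x 100 cells x 500 genes for the
planted-pathway characterization. These sizes keep a full run in the
low minutes on one core while leaving each check's failure modes
(enumeration mismatch, broken conservation, cross-super merges, wrong
top pathway) clearly visible.

## Known limitations

* The rule table covers the five canonical histone marks; open
  chromatin and DNA methylation require a user-supplied table.
* The running-sum statistic is unweighted and its permutation null
  permutes gene labels; sample-permutation nulls and weighted scores
  are out of scope.
* Identifier handling is a single optional two-column mapping applied
  at load; there is no automatic identifier-type detection.
* The single-cell workflow consumes precomputed annotations; it does
  not embed, cluster, or order cells itself.
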