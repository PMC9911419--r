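---
title: "Network-guided differential co-expression biclustering: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-guided differential co-expression biclustering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Classical clustering (k-means, hierarchical clustering) groups genes by
their behaviour across *all* samples. In heterogeneous cohorts — the
motivating case is transcriptome data from patients whose disease has
different genetic causes — a gene module may be co-expressed in only a
subset of samples and indistinguishable from noise elsewhere. Finding
such modules is a biclustering problem: select a gene set *and* the
sample set on which it co-behaves.

`cobinet` implements a network-guided differential co-expression
biclustering pipeline. Rather than testing all gene pairs, candidate
pairs are restricted to the edges of a gene interaction network (e.g. a
STRING export), which both cuts the search space quadratically and
focuses the method on biologically plausible modules.

## Pipeline overview

1. **Preprocessing** (`knn_impute()`, `normalize_per_gene()`): missing
   values are imputed by k-nearest-neighbour averaging (nan-Euclidean
   distance over co-observed samples, `k = 10` by default), then every
   gene is z-scored (population SD). Constant genes become all-zero
   rows; they carry no differential signal and are harmless downstream.
2. **Edge screening** (`screen_network_edges()`): for every network edge,
   rank-rank hypergeometric overlap (RRHO) finds the sample set on which
   the two genes are concordantly extreme, and a signal-to-noise ratio (SNR)
   measures how differential that set is. Edges failing either test are
   discarded.
3. **Module inference** (`run_gibbs()`): surviving edges are grouped by a
   collapsed Gibbs sampler for a finite Bernoulli mixture over the binary
   edge-by-sample membership matrix.
4. **Merging** (`iterative_merge()`): edge modules are converted to
   biclusters and iteratively merged when their sample sets overlap more
   than chance allows, under a sample-fraction cap and an SNR floor.

## Edge screening

### The SNR score

For gene $g$ and sample set $P'$ with complement $\bar{P}'$:

$$\mathrm{SNR}(g, P') = \frac{\mu_{g,P'} - \mu_{g,\bar{P}'}}
  {\sigma_{g,P'} + \sigma_{g,\bar{P}'}}$$

with population standard deviations. A set's SNR is the mean over its
genes. The exported `gene_snr()` returns the absolute value by default
(a set and its complement describe the same split), with
`signed = TRUE` available where the orientation matters. Two numerical
conventions are global: population SD (divisor $n$) everywhere, and a
guard that inflates a near-zero denominator by
$10^{-12}(1 + |\mu_{\text{in}} - \mu_{\text{out}}|)$ so degenerate sets
yield large-but-finite scores instead of infinities.

### RRHO

For an edge $(g_1, g_2)$ the samples are ranked by each gene's
expression (descending; ties broken by sample index, so results are
deterministic). For every prefix-length pair $(i, j)$ with
$i, j \in \{2, \dots, n-2\}$ — singleton prefixes are excluded as pure
noise — the overlap $o$ of the two prefixes is scored by the upper-tail
hypergeometric probability $P[X \ge o]$. The minimising cell defines the
edge's sample set (the prefix intersection), its p-value, and its
direction. Ties in $p$ go to the smaller $i + j$, then to the
concordant-high corner; gene pairs are canonicalised lexicographically
before scanning so the result cannot depend on argument order.

Both concordant corners are scanned by default: top-vs-top (both genes
high on the set) and bottom-vs-bottom (both low), so down-co-expressed
modules are detectable; the direction is recorded per edge. The two
corners are not independent for a module spanning about half the
samples — its set and its complement describe the same split from
opposite sides, and which corner wins is then close to a coin flip per
edge, which is the main accuracy cost at such sizes (the sampler splits
the module into a direct and a complement component that cannot merge).
`screen_config(both_tails = FALSE)` restricts screening to the high
corner, removing that ambiguity for up-module studies at the cost of
missing down-co-expressed sets.

The per-edge minimum is taken over a large dependent family of cells and
is deliberately left uncorrected (the calibrated operating point applies
a raw $p \le 0.01$ cut); `bh_correct = TRUE` optionally applies
Benjamini–Hochberg across edges.

### The data-driven SNR threshold

The retention threshold is derived from the data unless given
explicitly: for every edge the samples are Ward-bipartitioned on the two
genes' expression, the branch with the higher signed SNR among branches
holding under 55% of samples is taken as the edge's preliminary set, and
the threshold is **half the mean** preliminary-set SNR over all edges.
On the synthetic benchmark this lands around 0.4–0.45; it adapts to the
overall noise level of a dataset.

## Module inference: collapsed Gibbs sampling

Each retained edge $j$ contributes a binary row $x_{j\cdot}$ over
samples ($x_{ji} = 1$ iff sample $i$ is in edge $j$'s RRHO set). Rows
are modelled as a $K$-component Bernoulli mixture:

$$x_{ji} \mid s_j = k \sim \mathrm{Bernoulli}(\theta_{ki}), \quad
  \theta_{ki} \sim \mathrm{Beta}(\alpha/2, \alpha/2), \quad
  s_j \mid m \sim \mathrm{Categorical}(m), \quad
  m \sim \mathrm{Dirichlet}(\beta/K, \dots, \beta/K).$$

Integrating out $\theta$ and $m$ gives the collapsed label conditional

$$P(s_j = k \mid X, s_{-j}) \propto
  \frac{n_k^{-j} + \beta/K}{n - 1 + \beta}
  \prod_{i: x_{ji} = 1} \frac{\alpha/2 + c^{1,-j}_{ki}}{\alpha + n_k^{-j}}
  \prod_{i: x_{ji} = 0} \frac{\alpha/2 + c^{0,-j}_{ki}}{\alpha + n_k^{-j}}$$

where $n_k^{-j}$ counts the edges in component $k$ and $c^{1,-j}_{ki}$ /
$c^{0,-j}_{ki}$ the member edges with a one / zero at sample $i$, all
excluding edge $j$. `conditional_weights()` is the direct reference
implementation; the compiled sweep kernel uses an algebraically
identical incremental form (per-component cached base terms, log tables
over integer counts, log-sum-exp with max subtraction) and is tested
against both the reference and, on tiny instances, the exactly
enumerated collapsed posterior (total-variation distance below 0.02).

Choices where the model family leaves room:

* **$K$** defaults to the number of connected components of the
  retained-edge network — the only cluster structure available at that
  stage — and can be overridden.
* **Sweep schedule**: fixed edge order, 500 sweeps with 250 burn-in.
  On benchmark-sized instances the label trace stabilises within a few
  dozen sweeps; the defaults leave a wide margin.
* **Point estimate**: each edge's *modal* label over post-burn-in sweeps
  (marginal mode), which is markedly more stable across seeds than the
  final sweep.
* **Reproducibility**: the sampler draws from R's RNG, so a fixed seed
  gives bit-identical runs; the pipeline derives per-stage seeds from
  one global seed via a stable stage-name hash, letting stages be rerun
  in isolation.

Edge modules become biclusters (`extract_modules()`): the gene set is
the union of the member edges' endpoints; the sample set keeps samples
whose posterior membership rate $(c^1_{ki} + \alpha/2)/(n_k + \alpha)$
exceeds $1/2$. Components whose consensus set is empty or spans all
samples are degenerate and dropped with a warning.

One refinement matters in practice: an edge between a module gene and an
unrelated gene can pass screening on the strength of the module gene
alone (its RRHO set sits inside the module's samples), joining the
module's component and dragging the unrelated endpoint into the gene
union. The pipeline therefore keeps a gene only if it is itself
differentially expressed on the component's consensus sample set (Welch
t-test, in-set vs out-set, at the screening significance level), at
extraction and again after merging. The level is uncritical — genuinely
differential genes sit tens of orders of magnitude below it, while
hitchhikers are uniform — and an SNR cut deliberately is *not* used
here: a gene shared by two overlapping planted modules has a deflated
SNR on either module's set (its out-set mean is inflated by the other
module) yet is unambiguously differential, and a t-test keeps it where
an SNR threshold would not.

## Merging

Two biclusters merge when three conditions hold:

1. **Similarity gate.** Their sample sets overlap significantly more
   than chance: one-sided Fisher exact test (positive association),
   $p \le \alpha_F$ with $\alpha_F = 0.05$. The gate direction deserves
   a note: fragments of one true module have near-identical sample sets,
   i.e. an overlap many orders of magnitude beyond chance, while two
   unrelated modules have *independent* sample sets. A gate that merged
   whenever the sets were "not significantly different" in the two-sided
   sense would treat independence (p near 1) as licence to merge and
   reject identical sets; the positive-association direction does the
   opposite, which is what a merge step must do. Because the pair family
   grows quadratically, `iterative_merge()` Bonferroni-adjusts
   $\alpha_F$ by the number of pairs in each pass (configurable off):
   genuine fragments sit at $p < 10^{-20}$ and always clear it, while
   chance-high overlaps between unrelated clusters (about 5% of pairs at
   a raw 0.05) no longer destroy both partners.
2. **Sample-fraction cap.** The merged gene set is Ward-bipartitioned
   over the samples and the branch with the higher signed SNR among
   branches holding under 55% of samples becomes the candidate set. The
   cap exists because a set covering about half the samples is
   differential relative to either side; the signed selection picks the
   up-expressed side, which keeps a candidate from silently flipping to
   the complement when both branches clear the cap.
3. **SNR floor.** The candidate's (absolute) set SNR must exceed the
   screening threshold.

Passes repeat until a full pass accepts no merge; within each pass,
pairs are attempted in ascending Fisher-p order, which makes the greedy
procedure deterministic. Rejected pairs are reconsidered in later passes
because earlier merges change the landscape. Termination is guaranteed:
every accepted merge reduces the cluster count by one. Final pipeline
outputs are filtered to the structural constraints (cap and SNR floor,
recomputed from the matrix).

## The synthetic benchmark

`generate_dataset()` emulates the study conditions the method was
calibrated under: a 2000-gene by 200-sample matrix, 20 planted modules
with gene counts drawn from {100, 50, 20, 10, 5} and sample counts from
{100, 50, 20, 10} (or a fixed size for table-style runs), in-module
cells from $N(2, 1)$, background from $N(0, 1)$, overlaps permitted
(later modules overwrite earlier ones on shared cells).
`generate_network()` builds the companion network: a uniform random
spanning tree per module (so every planted module is connected) plus
random in-module edges up to mean degree 3, and background edges between
arbitrary genes at mean degree 1. The degree targets are exposed; the
spanning-tree construction realises the "compact but not tightly
connected" shape disease modules show on interaction networks.

What the generator does *not* emulate: heavy-tailed or probe-level
microarray noise, batch effects, correlated backgrounds, or modules
defined by correlation without a mean shift. Passing benchmarks here
demonstrates recovery of mean-shifted Gaussian blocks guided by a
partially informative network — not robustness to those artefacts.

Evaluation (`recovery_score()`) is by cell-level Jaccard: clusters are
compared as sets of (gene, sample) cells, so a method is rewarded for
sample accuracy as well as gene accuracy. *Recovery* (mean over true
modules of the best-matching found cluster) is the headline number;
*relevance* (the dual) is reported alongside, and per-size group means
support size-stratified summaries. Recovery is deliberately insensitive
to extra junk clusters; relevance is the number to watch if those
matter.

## Problem sizes and determinism

The test suite runs the statistical oracles exhaustively (all universes
up to 12 for the hypergeometric and Fisher enumerations; 50,000 sweeps
for the sampler-vs-posterior check) and a scaled benchmark (two
replicates of two configurations plus sanity runs). The acceptance
script `scripts/acceptance.R` runs the full five-replicate protocol for
five fixed-size configurations. A full 2000x200 pipeline run takes
roughly 20-30 s on one core; the sampler and the RRHO grid scan are
compiled, everything else is plain R on top of `stats` and `igraph`.

## Known limitations

* Screening retains some spurious edges by construction: the per-edge
  minimum p over the RRHO grid is uncorrected, and sets selected at the
  extremes of two rankings have inflated SNR. The mixture model isolates
  most such edges in their own components, and recovery is unaffected,
  but junk biclusters do appear in the output (low relevance); they are
  cheap to filter post hoc by size or SNR.
* Modules spanning about half the samples are each reported partly
  through their sample set and partly through its complement (the
  corner ambiguity above); `both_tails = FALSE` removes this for
  cohorts where only up-modules matter.
* Modules covering well over half the samples are outside the method's
  contract (the 55% cap) — by design, following the differential
  reading of "module".
* $K$ from connected components undercounts when distinct modules share
  retained edges; the sampler tolerates moderate undercounts by reusing
  emptied components, but a severe undercount merges modules.
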