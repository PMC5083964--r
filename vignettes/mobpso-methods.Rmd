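---
title: "Methods: multi-objective binary PSO gene-subset selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-objective binary PSO gene-subset selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobpso)
```

## The problem and the model

Two-class expression studies (tumour vs normal tissue, lymphoma subtypes,
leukaemia lineages) measure thousands of genes on a few dozen arrays. Most
genes are irrelevant to the class distinction, and classifiers built on the
full matrix are noisy and uninterpretable. The goal here is a *minimal
feature subset* in the rough-set sense: the smallest sets of genes that can
still tell every pair of samples from different classes apart.

The pipeline has three stages.

**1. Discretization.** Each gene is min-max normalized to $[0,1]$ across
samples; constant genes are dropped (they can never discern anything). Per
gene, a grouped-frequency grid with `n_intervals` equal classes of width
$\delta = 1/\texttt{n\_intervals}$ yields interpolated quartile partition
values

$$\mathrm{PV}_k = l_c + \frac{R_k - \mathrm{cfr}_{c-1}}{\mathrm{fr}_c}\,
\delta, \qquad R_k = \frac{k\,n}{4},\; k = 1,2,3,$$

where $c$ is the lowest class interval whose cumulative frequency reaches
$R_k$, $l_c$ its lower limit and $\mathrm{fr}_c$ its frequency. The first
and third partition values become the low/high thresholds
$Th_i = \mathrm{PV}_1$, $Th_f = \mathrm{PV}_3$, and each value is ternarized:
$\le Th_i$ is `0` (low), $\ge Th_f$ is `1` (high), anything strictly between
is `*` (don't care). The low branch is tested first, so a value sitting on
coincident thresholds maps to `0`. Genes whose `*`-count reaches the mean
`*`-count across genes ($Th_a$, non-strict comparison) are removed as
ambiguously expressed; a single-gene table skips this filter because a mean
threshold over one observation is vacuous.

**2. The distinction table.** For every pair of samples from different
classes there is one row; the entry for gene $i$ is 1 exactly when both
samples carry definite, differing symbols for $i$. With two classes of sizes
$C_1$ and $C_2$ the table has $C_1 C_2$ rows; with $k$ classes, every
unordered class pair contributes the product of its sizes. Same-class pairs
are never represented — this is what keeps the table tractable. Rows that no
gene discerns are *kept*: they cap the attainable coverage below 1 and
deleting them would silently overstate discernibility. A *reduct* is a
column subset covering every row.

**3. The search.** Candidate subsets are bit vectors $v$ of length $N$
scored on two conflicting objectives, both maximized:

$$\mathrm{Fit}_1(v) = \frac{N - O_v}{N}, \qquad
\mathrm{Fit}_2(v) = \frac{R_v}{\text{rows}},$$

with $O_v$ the subset cardinality and $R_v$ the number of rows covered. A
binary particle swarm explores this space: velocities follow the canonical
inertia-weighted rule
$v \leftarrow w v + c_1 r_1 (\mathrm{pbest} - x) + c_2 r_2 (\mathrm{gbest} - x)$
clamped to $[v_{\min}, v_{\max}]$, and each position bit is resampled as
Bernoulli with probability $S(v_i) = 1/(1+e^{-v_i})$ (the sigmoid transfer
of binary PSO). Selection is Pareto-based: the combined parent + offspring
population is ranked by non-dominated sorting and only the best 50 % survive.
An external archive accumulates every rank-1 solution encountered, pruned to
mutual non-domination; this archive is the reported Pareto front. A weighted
scalarization $\mathrm{Fit}_1\alpha + \mathrm{Fit}_2(1-\alpha)$ is exposed
for single-objective comparisons but is not used by the search.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_intervals` | 10 | grid resolution for the quartile thresholds; $\delta = 0.1$ on the normalized scale |
| `swarm_size` (P) | 20 | particles per generation (even; 50 % survival conserves it) |
| `generations` (G) | 50 | search length |
| `w` | 0.9 | inertia weight; high values favour exploration |
| `c1`, `c2` | 2, 2 | cognitive / social acceleration |
| `v_min`, `v_max` | −4, 4 | velocity clamp; bounds bit probabilities to $[0.018, 0.982]$ |
| `k` (validation) | 1 | odd neighbour count for k-NN, avoiding two-class vote ties |
| `folds` | 10 | stratified cross-validation folds |

These defaults are the standard published settings for this optimizer
family; all are overridable through `mobpso()`, `mobpso_config()` and the
CLI.

## Design choices where the design was open

* **Quartile pair.** "Based on the idea of quartiles" fixes the grid but not
  which partition values bound the don't-care band; the first/third pair is
  the only choice producing a low/high/ambiguous split, so
  $Th_i = \mathrm{PV}_1$, $Th_f = \mathrm{PV}_3$.
* **Per-gene grids.** Thresholds are computed attribute-wise, matching the
  attribute-wise normalization.
* **Ambiguity filter comparison** is non-strict (`>= Th_a` removes), as the
  rule is stated.
* **Guide selection.** All rank-1 solutions have equal priority, so the
  guide is a uniform draw from the rank-1 set — and *each particle draws its
  own*, the convention of the multi-objective swarm literature with an
  external repository. Independent draws spread the social pull across the
  whole current front; with a single shared guide per generation the swarm
  measurably under-covers the sparse end of the front on small instances.
* **Personal best under incomparability** is replaced with probability 0.5
  (seeded) — dominance alone cannot order incomparable pairs, and a fair
  coin avoids a systematic drift toward either objective.
* **Boundary-rank tie-break** in environmental selection is deterministic:
  descending coverage, then descending parsimony, then first-seen order. No
  crowding distance is used anywhere.
* **Row ordering** of the distinction table is lexicographic by (class pair,
  first sample, second sample), making runs byte-reproducible under a seed.
* **All-zero rows are retained** so that $\mathrm{Fit}_2 = 1$ is attainable
  exactly when a true reduct exists.

## The synthetic generator

`synthetic_spec()` / `generate_dataset()` emulate a two-class expression
matrix with a *known* minimal covering subset, so every claim about the
pipeline can be checked against ground truth. Class B's samples are
partitioned into $m$ blocks; informative gene $i$ is expressed high on block
$i$ and low everywhere else, so it discerns exactly the (class A × block
$i$) pairs and the minimal reduct has size exactly $m$. Noise genes are
uniform on $[0,1]$ and are mostly removed by the ambiguity filter, since
roughly half of each noise gene's values fall between its own quartiles.

In **ideal** mode the two expression levels are exact (0.1 and 0.9). This is
deliberate: with continuous draws, a gene's own quartile thresholds fall
*inside* whichever value cluster holds the quartile ranks, which stars
mid-range values and can star informative genes whenever one class is small.
Two-level profiles normalize to exactly $\{0, 1\}$ and ternarize definitely
under any quartile estimate, decoupling generator correctness from
discretization detail. **Noisy** mode adds Gaussian jitter (`noise_sd`,
default 0.05) and clips to $[0,1]$.

Default sizes — 30 genes, 3 informative, classes of 22 and 40 — mirror a
typical two-class colon-cancer-sized study and give every class enough
members for stratified 10-fold validation.

What the generator does *not* emulate: spot artifacts, dye bias, batch
effects, correlated noise genes, or class-imbalance pathologies. Passing
tests on this generator show the machinery is correct, not that any
particular real dataset will yield small reducts.

## Numerical and degenerate-input conventions

* Value exactly 1.0 falls in the last (closed) grid interval.
* A quartile rank on a boundary shared with an empty class interval resolves
  to the lowest interval whose cumulative frequency reaches the rank, which
  also guarantees a nonzero interval frequency in the interpolation.
* Grouped quartiles track sort-based quantiles to within $\delta$ once
  samples are dense enough that no interval around the quartile ranks is
  empty (40+ samples on a decile grid); for very small sample counts only
  monotonicity and range are guaranteed.
* Constant genes error out of normalization only when *all* genes are
  constant; otherwise they are dropped and logged.
* k-NN breaks distance ties by training order and multi-class vote ties by
  the nearest tied-label neighbour; `k` must be odd.
* Z-scores standardize within sample across *all* genes with the population
  (divide-by-$n$) standard deviation; a constant sample is an error.
* The exhaustive Pareto oracle is guarded to $N \le 20$ features.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
the 7-feature worked-example table, random distinction tables with up to 12
features and 20 rows (where exhaustive enumeration over all $2^N$ subsets
is exact), 500 random populations of up to 64 objective pairs for the
sorting oracle, and generator defaults (30 × 62) for recovery and
cross-validation checks. These sizes make every oracle exact while keeping
a full run in the tens of seconds.

## Known limitations

* The swarm is stochastic; on dense 12-feature tables a single run
  occasionally misses one extreme of the exact front (most often the empty
  subset, which nothing in the dynamics is attracted to). Multiple restarts
  with different seeds are the practical remedy.
* Post-filter gene counts depend on `n_intervals`; there is no universally
  correct grid width, and published counts for the classic benchmark
  datasets cannot be reproduced without knowing the width used.
* Missing intensities are rejected, not imputed.
* Only k-NN is built in; other classifier families plug in through the
  `fit`/`predict` adapter of `cross_validate()` as external validation.
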