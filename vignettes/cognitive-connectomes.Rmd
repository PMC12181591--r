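---
title: "Cognitive connectomes: model, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive connectomes: model, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cognectome)
```

## The model

A *cognitive connectome* is a network whose nodes are the variables of a
neuropsychological battery — here 47 variables in five cognitive modules
(verbal memory, VM; visual memory and visuospatial functions, VMV;
executive and premotor functions, EPF; procedural memory, PM; processing
speed, PS) — and whose edges are between-participant Pearson
correlations of those variables within one subgroup of a cohort. There
is no individual-level connectome in this framework: the correlation is
a group property, which is why group comparisons require permutation
inference over participants.

The pipeline assumes a six-cell design: age bins EMA (37–50), LMA
(51–64) and ELD (65–78 years), each split into high and low cognitive
reserve by a threshold on the WAIS-III Information score (high:
score > threshold; the canonical threshold is 15, the package defaults
to the cohort median and reports it).

For each group, scores are whole-cohort z-scores with the PM and PS
variables inverted (their raw scores are times/errors, where larger
means worse). The weighted connectome is

$$w_{ij} = \max(0, r_{ij}), \qquad w_{ii} = 0,$$

with negative correlations *removed* (set to zero, not folded in by
absolute value — an absent edge, not a strong one). Binary graphs are
obtained by proportional thresholding: at target density $d$ the
$k = \mathrm{round}(d\,n(n-1)/2)$ strongest positive edges are kept.
Matching edge counts across groups is what makes topological comparisons
meaningful; an r-value cut would confound topology with overall
correlation level. Rounding is half-away-from-zero, and ties are broken
by descending weight then ascending label order, making the stack of
graphs over the density grid (20–60% in 1% steps, 41 levels) *nested*
and fully reproducible. Connectivity is therefore monotone in density,
and global efficiency never decreases along the stack.

The density range itself can be recomputed for a new cohort with
`select_density_range()`: the lower end excludes disconnected pooled
graphs, the upper end excludes random topology (small-worldness < 1).

## The five global measures

* **Network strength** — mean over nodes of the sum of edge weights;
  the only measure computed on the weighted matrix.
* **Global efficiency** — mean of $1/d_{ij}$ over ordered pairs,
  unreachable pairs contributing 0 (so it is defined on disconnected
  graphs).
* **Local efficiency** — mean over nodes of the global efficiency of the
  neighbor-induced subgraph; degree < 2 contributes 0.
* **Modularity** — $Q$ of the partition found by Newman's
  leading-eigenvector algorithm (Louvain available via
  `modularity_q(..., method = "louvain")`). The spectral algorithm
  starts from the single-community partition ($Q = 0$) and only accepts
  improving splits, so $Q \ge 0$ always; it is a heuristic and is not
  guaranteed to attain the global optimum, which is why the test suite
  checks it against exhaustive enumeration only for near-optimality and
  against planted two-clique graphs for exactness.
* **Small-worldness** — $\sigma = (C/C_{rand})/(L/L_{rand})$ with $C$
  the mean local clustering coefficient and $L$ the mean shortest path
  over connected ordered pairs. The null ensemble is degree-preserving
  double-edge-swap randomization ($10\,|E|$ attempted swaps per
  reference graph), the standard null in connectomics; an Erdős–Rényi
  null would confound degree heterogeneity with small-world structure.
  Graphs the rewiring cannot alter (complete graphs) give $\sigma = 1$
  exactly.

Path length on disconnected graphs is averaged over reachable pairs
(with the unreachable count reported) — an efficiency-style convention
needed because graphs below the selected range can be disconnected.

## Permutation inference and the stability rule

For two groups A and B, the observed statistic at each density is
$\Delta(d) = m_A(d) - m_B(d)$. The null re-splits the pooled
participants into groups of the original sizes uniformly at random —
participants are the only exchangeable unit for group-level correlation
networks — rebuilding both connectomes and re-thresholding at the same
densities each time. Two-tailed p-values use the add-one convention
$p = (1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\})/(1 + n_{perm})$,
which can never be 0. Defaults are 1000 permutations, 100 for
small-worldness (whose inner rewiring ensemble is reduced to 10
reference graphs per evaluation, recorded in the result metadata).

A comparison is *stable-significant* when p < 0.05 at ≥ 10 of the 41
densities. Strength has no density axis; its single p-value is compared
to α directly, and the ≥ 10 rule applies only to density-resolved
measures. No multiplicity correction is applied across the 9 × 5 design
beyond the stability rule, matching standard practice for this analysis;
the pooled groups are compared pairwise, and each comparison's seed is
derived from the master seed by a fixed counter so that adding
comparisons never shifts existing ones.

Internally the pooled pair is ordered canonically (smaller group first,
content tiebreak) before resampling, which makes the label-swap identity
exact: swapping A and B negates every observed difference and leaves
every p-value unchanged.

## The MANOVA stage

Cognitive performance per participant is summarised by five module
composites (means of inverted z-scores). The age × reserve interaction
is tested with Wilks' Λ and Rao's F approximation; with five responses
and a 2-df interaction this gives the familiar F(10, N − 6 − …) shape
(F(10, 648) at N = 334). Sums of squares are type II by default
(type III differs only for main effects; the highest-order interaction
is identical) because the six cells are unbalanced by design. Canonical
discriminant functions of the interaction are returned with their signs
fixed so that higher cognitive performance loads positive. A sensitivity
model adding sex tests the three-way interaction. Follow-up univariate
ANOVAs report the interaction per module.

## The synthetic-cohort generator

No public accession exists for cohorts of this kind, so the generator is
a first-class module. Each group's 47 variables follow a multivariate
normal whose correlation matrix is block-constant on the *analysis*
orientation: `r_intra` for same-module pairs, `r_inter` for cross-module
pairs, 1 on the diagonal. Raw scores of the time-like PM/PS variables
are the negated latent score, so on the raw scale their correlations
with ability scores come out negative, as in real batteries; downstream
inversion restores the block structure. A Gaussian model is exactly the
structure that Pearson-correlation connectomes and z-scoring assume, so
it exercises every pipeline stage without adding unmodelled features.
Block-constant correlations (one `r_intra`/`r_inter` pair per group)
reproduce every qualitative regime of interest; a full-matrix override
(`sigma_override`) exists for anything richer. The constructor verifies
positive semidefiniteness of every implied matrix (smallest eigenvalue
≥ −1e−10) and rejects otherwise, naming the group; eigenvalue clipping
is available only by explicit opt-in.

Defaults are the reference study conditions: group sizes
59/67/40/51/39/78 (total 334; age-bin totals 110/106/118), module mean
shifts equal to the published per-group module-composite means (read on
the raw orientation, where elderly groups have the largest
processing-speed scores because raw speed scores are times), % women,
MMSE means/SDs per group, WAIS-III Information drawn uniformly in the
reserve band (high 16–26, low 4–15), ages uniform in the bin. The
correlation dials are not published; the defaults keep the three
high-reserve groups identical (0.5/0.2) and vary the low-reserve groups
(EMA 0.45/0.15, LMA 0.60/0.45, ELD 0.30/0.10), mirroring the described
stability of the high-reserve connectome and the late-middle-age
dedifferentiation in low reserve. These were fixed once, from the
qualitative description, as the generator's study conditions.
Demographic screeners (BDRS, FAQ) are drawn so that generated cohorts
pass eligibility; the screen itself is exercised by constructed cases in
the tests.

Three named fixtures drive validation (`make_fixture()`):

* `"null"` — all groups share one parameter set; any detected difference
  is a false positive. Used to verify that per-density rejection runs at
  α and that the stability rule flags only a small fraction of
  comparisons.
* `"dedifferentiation"` — one group (LMA low-reserve) has `r_inter`
  raised to 0.9 × `r_intra`, blurring the modular structure; modularity
  and small-worldness comparisons against an unaltered group must
  recover the planted effect.
* `"stable_reserve"` — high-reserve groups share parameters, low-reserve
  groups differ across age; within-high age contrasts must stay quieter
  than within-low ones.

What the generator does **not** emulate: non-Gaussian score
distributions (floor/ceiling effects, skewed error counts), item-level
structure, missing data patterns, longitudinal dependence, and
correlation between demographics and cognitive scores beyond the
group-level mean shifts. Passing tests therefore demonstrate that the
*pipeline* is correct and calibrated under its own assumptions, not that
those assumptions hold in any particular clinical cohort.

## Numerical conventions and degenerate inputs

* z-scoring uses the sample SD (n − 1) by default; the population
  convention is available (`sd_type = "population"`). The difference is
  third-decimal at cohort sizes. Zero-variance variables are an error,
  named.
* Missing scores: complete-case with a message; preprocessing errors if
  any stratified cell would lose > 10% of participants.
* Ages are floored to integers before binning (bins are closed integer
  intervals); out-of-range ages are an error listing ids.
* The reserve threshold defaults to the cohort median (reported); the
  canonical 15 is a cohort-specific value, reproduced by passing
  `threshold = 15`.
* Fewer positive edges than k at some density: all positive edges are
  kept and the realized density recorded.
* Edgeless graphs: modularity errors (undefined); efficiency is 0.
* Degenerate rewiring (rigid graphs): σ falls back to 1.
* All stochastic steps (generation, permutation, rewiring, spectral
  tie-breaks) run under explicit integer seeds; rewiring uses a
  portable xorshift generator seeded from R's RNG, so results are
  bit-reproducible across platforms for a fixed seed.

## Problem sizes used in the shipped validation

The test suite sizes its simulations as the package's own validation
design: graph-oracle equivalence on 520 seeded graphs of 4–8 nodes
(tolerance 1e−12); null calibration on 200 replicate cohorts at 40
participants per group with 500 permutations of the global-efficiency
comparison over two disjoint group pairs; planted-effect recovery on 20
replicates at 50 per group with 100 permutations (modularity, and
small-worldness with a 5-graph rewiring ensemble); and the
stable-reserve trend on 20 replicates at 40 per group with 200
permutations of strength and global efficiency. The acceptance script
reruns the full default cohort (334 participants) with a 200-permutation
design over strength and global efficiency.

## Known limitations

* Group-level inference only; no individual connectomes, partial
  correlations, or covariate-adjusted edges.
* The five global measures only; no nodal, edge-level or weighted-graph
  statistics beyond strength.
* The leading-eigenvector partition is a heuristic; for publication-
  grade modularity optima on small graphs, exhaustive or exact solvers
  would be needed.
* The stability rule is a pragmatic filter, not a formal multiplicity
  correction; FDR across the design is available as an option but off
  by default to match the reference analysis.
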