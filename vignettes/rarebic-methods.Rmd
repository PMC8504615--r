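---
title: "Methods: constrained max-sum biclustering for rare subpopulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained max-sum biclustering for rare subpopulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarebic)
```

## The optimization problem

`rarebic` looks for a small group of cells together with the genes that
mark it. Given a signed log-expression matrix $M \in \mathbb{R}^{|G| \times |C|}$
(positive = expressed, negative = negligibly expressed), it maximizes over
gene sets $I$ and cell sets $J$

$$\sum_{i \in I} \Big( \sum_{j \in J} m_{ij} \;-\; \kappa \sum_{k \in C
\setminus J} \max(0, m_{ik}) \Big)
\quad \text{s.t.} \quad
\frac{|\{(i,j) \in I \times J : m_{ij} < 0\}|}{|I|\,|J|} \le \mu .$$

The sum criterion tolerates within-bicluster variation (technical and
biological noise, transcriptional bursting) because entries are never
compared pairwise; only the aggregate matters. The penalty term makes the
solution *specific*: a gene that is also expressed outside the candidate
cell group pays for every positive out-of-cluster entry. The $\mu$
constraint caps how many non-expressed entries the bicluster may absorb,
which is the mechanism that accommodates dropout without letting the
solution degenerate.

Assumptions worth stating explicitly:

* the matrix is sign-calibrated — zero is the "expressed" threshold. The
  default `log_normalize()` transform $\log_{10}(x + 0.1)$ encodes a raw
  count threshold of $0.9$; zero counts map to $-1$;
* inputs are count-comparable across cells. The package does no per-cell
  depth normalization or cell quality control;
* the interesting signal is *high* expression in a *small* group. Genes
  expressed in more than `max_prevalence` of cells (default 25%) are
  removed before the search: they cannot mark a rare subpopulation, and
  keeping them would reward large unspecific biclusters.

## Parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `kappa` | $100/|C|$ | $\ge 0$ | weight of the out-of-cluster penalty; higher values select fewer, more specific genes. Around 20 selected marker genes is a practical target when tuning. |
| `mu` | 0.10 | fraction | budget of negative entries inside the bicluster; raise it for data with heavy dropout. |
| `max_prevalence` | 0.25 | fraction | gene prevalence filter; boundary inclusive (a gene expressed in exactly 25% of cells is kept). |
| `pseudo` | 0.1 | counts | pseudo-count of the log transform; the raw expression threshold is $1 - $ `pseudo`. An explicit `threshold` mode subtracts $\log_{10}(t + \mathrm{pseudo})$ instead. |
| `beam_width` | 100 | sets | frontier size of the breadth-first search. |
| `patience` | 2 | levels | stop after this many levels without improvement of the best feasible objective. |
| `min_cells` / `max_cells` | 2 / all | cells | bicluster size bounds; the search starts from cell pairs. |

## Gene selection for a fixed cell set

With the cells fixed, the objective is additive over genes: gene $i$
contributes its *gain* $\sum_{j \in J} m_{ij} - \kappa \sum_{k \notin J}
\max(0, m_{ik})$. Unconstrained ($\mu = 1$) the optimum is exactly the
positive-gain set, found in linear time. Zero-gain genes are excluded (they
only consume the $\mu$ budget and inflate the gene list) and negative-gain
genes are never included, even though in principle a negative-gain gene
with no negative entries could "buy" feasibility for others — that variant
would make the subproblem a knapsack and break the linear-time structure.

Under the constraint ($\mu < 1$) the default rule is greedy: sort the
positive-gain genes by ascending in-cluster negative count (ties broken by
descending gain, then input order) and keep the longest feasible prefix.
Because the running mean of a sorted sequence is non-decreasing, prefix
feasibility is monotone and the rule never violates the constraint.
`select_genes(..., exact = TRUE)` instead enumerates subsets of the
positive-gain candidates (capped at 20) and returns the constrained
optimum; the test suite uses it to measure the price of the greedy rule on
small random instances, where the observed gap is essentially zero.

## The search over cell subsets

A naive search would enumerate $2^{|G| + |C|}$ biclusters; fixing the cells
reduces it to $O(|G| \cdot 2^{|C|})$, still exponential. The solver is a
breadth-first beam: evaluate all $\binom{|C|}{2}$ cell pairs, keep the best
`beam_width` sets, and at each subsequent level extend every retained set by
one cell (supersets only, deduplicated, statistics updated incrementally by
adding one column — the tests verify incremental and from-scratch
evaluations agree). Candidate evaluations are therefore
$O(\text{beam\_width} \cdot |C|^2)$, which the test suite asserts by
counting them.

Two design choices in the frontier ordering are worth recording, because
neither follows from the objective alone:

* **Ranking candidates without a feasible gene set.** With the default
  $\kappa = 100/|C|$, a pair of cells drawn from a genuinely rare
  subpopulation often has *no* positive-gain gene: most of the marker mass
  sits in the other rare cells, which at level 2 still count as
  out-of-cluster. Ranking such "invalid" candidates below all valid ones
  but *among themselves* by the gain of their best singleton-feasible gene
  (a gene with $\text{neg} \le \mu |J|$, i.e. positive across the whole
  candidate) lets the beam walk through this regime deterministically: rare
  pairs score far above arbitrary background pairs, reach the level where
  their gains turn positive, and the planted optimum is found. Candidates
  with no finite score are dropped from the frontier.
* **Stopping.** The best feasible objective typically rises steeply while
  the true subpopulation is being assembled and drops once unrelated cells
  are appended, so the search stops after `patience = 2` levels without
  improvement — counted only once a feasible bicluster exists, since early
  levels of a rare-population search can be entirely infeasible.

`exhaustive_search()` enumerates all cell subsets (guarded at 20 cells) and
breaks ties toward fewer cells, then lexicographic order. By default it
uses the same greedy gene selection as the beam so the two are directly
comparable; `exact_genes = TRUE` upgrades it to exact constrained
selection. On 50 random 8–10-cell instances the beam at full width matches
the oracle on every instance, and at the default width on 96% of them,
never exceeding it.

`top_k()` removes the cells of each solution and re-runs the search on the
remainder, re-applying the prevalence filter so every round sees the same
preconditions as the first (prevalence is a property of the current cell
population; a gene can legitimately become filterable after a round). When
`kappa` is unset it is re-resolved as 100 over the remaining cell count.
Results are returned ordered by objective.

## The planted-subpopulation generator

`generate_planted()` emulates a controlled experiment: an abundant
background population plus one or more small planted subpopulations (at
least 5 cells each) with dedicated marker genes.

* **Counts** are negative binomial. Markers in their rare cells have mean
  `marker_mean = 50` with dispersion `size = 1` — deep, plate-based-scale
  counts with realistically heavy spread. Each marker read is zeroed
  independently with probability `dropout` (default 0.2).
* **Marker leakage**: a marker is spuriously expressed in a background cell
  with probability `background_rate = 0.01`.
* **Background noise**: every gene is expressed in any cell with
  probability `noise_rate = 0.005` at mean count 20 — scattered, unstructured
  noise, so that after log-normalization over 90% of entries are negative,
  as in prevalence-filtered single-cell data.
* **Defaults** pose the canonical task: 50 cells of which 5 (10%) are rare,
  1000 genes of which 20 are markers, matching the regime where roughly 20
  marker genes describe the subpopulation.

The generator reproduces the *structure* of the task — rarity, marker
specificity, dropout, sparsity — but deliberately not every feature of real
data: there are no cell-depth differences, no correlated gene modules in
the background, no heterogeneous marker prevalence inside the rare group,
and all markers share one mean. Passing the recovery suites therefore shows
the optimization does what it claims on cleanly posed instances; it does
not certify performance on any particular real dataset. Seeds are explicit:
run $r$ of a controlled experiment uses `design$seed + r - 1`, so reports
are reproducible end to end, and each run is judged by the returned bicluster with the highest
precision (ties: higher recall) — the candidate containing the largest
proportion of truly rare cells.
One caveat follows from that convention: enlarging the candidate pool from
top-1 to top-2 cannot lower the counts of 100%-precision runs, but the
*F1* of the precision-selected candidate is not formally monotone, so the
corresponding regression test allows a small tolerance.

## Numerical choices and degenerate inputs

* "Expressed" is strictly $> 0$; "negative" is strictly $< 0$. Entries at
  exactly zero are neutral on both sides, consistent with the strict
  inequality in the constraint.
* The prevalence boundary is inclusive (remove only *more than* 25%);
  feasibility is inclusive ($\le \mu$).
* All tie-breaks are deterministic (gain descending, then input order;
  frontier and enumeration order fixed), so identical inputs give identical
  outputs, and permuting rows/columns permutes the solution.
* A matrix with no feasible bicluster yields an explicit no-solution result
  carrying the search trace, not an error; the CLI exits 0 and writes an
  empty result list.
* Matrices that already contain negative values are treated as normalized
  and are not log-transformed again unless forced.

## Problem sizes used by the test and acceptance suites

The suites run the toy 15×12 example; 50 random oracle-comparison instances
of 8–10 cells × 12–20 genes; recovery experiments of 10 runs each at 50 and
200 cells (5 rare, 1000 genes); a dropout curve over $\{0, 0.2, 0.4\}$ at 50
cells; ten two-subpopulation instances of 60 cells; and search-cost scaling
at 20–100 cells. These sizes keep every suite deterministic and give clean
separation between the planted optimum and the noise floor.

## Limitations

The beam heuristic carries no optimality guarantee beyond the oracle
comparisons above; pathological instances can defeat a fixed width. The
constrained gene selection is greedy by default; its exact counterpart is
exponential and only practical for tens of candidate genes. Scaling is
quadratic in the number of cells, comfortable to ~1000 cells and
increasingly impractical beyond. The method targets jointly *highly
expressed* markers; finding jointly *silent* gene patterns would require
negating the matrix and re-calibrating the sign convention.
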