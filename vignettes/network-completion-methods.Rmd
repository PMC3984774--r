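---
title: "Completing gene regulatory networks from steady-state expression data"
author: "GRNcomplete authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Completing gene regulatory networks from steady-state expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GRNcomplete)
```

## The model

Static expression data — one measurement per sample, many samples — are
treated as observations of a stationary regulatory state. The stationary
expression $x_i$ of gene $v_i$ with regulators $v_{i_1},\dots,v_{i_h}$ is
modelled as a quadratic polynomial

$$x_i = a_0^i + \sum_{j=1}^{h} a_j^i x_{i_j}
      + \sum_{j \le k} a_{j,k}^i x_{i_j} x_{i_k} + b_i\,\omega,$$

with pure squares included in the product sum. Positive coefficients act
as activation, negative as inhibition, and the bilinear terms capture
cooperative regulation. The noise term $b_i\omega$ is never estimated:
fitting minimises the residual sum of squares over the $m$ samples

$$S^i_{i_1,\dots,i_h} = \sum_{s=1}^{m}
  \Big|y_i(s) - \big(a_0^i + \sum_j a_j^i\,y_{i_j}(s)
  + \sum_{j\le k} a_{j,k}^i\,y_{i_j}(s)\,y_{i_k}(s)\big)\Big|^2,$$

which is linear least squares in the coefficients, and the noise is
absorbed into the residual. A parent set of size $h$ has
$1 + h + h(h+1)/2$ coefficients; `designRow()` documents the fixed term
order $(1,1), (1,2), \dots, (h,h)$. Expression values are fitted raw — no
centering, scaling or log transform; any preprocessing is deliberately
left to the user.

Because the design includes the linear term of every declared parent, a
gene listed as its own parent (a self-loop) is fitted exactly by the
identity — the residual is zero whatever the noise. This is why the
candidate rule below excludes self-loop *additions* by default.

## Completion as a dynamic program over budgets

Completion modifies a given network by exactly $k$ additions and $h$
deletions so the summed residual over genes is minimal. Per gene $j$ and
per-gene budget $(k_j \le K, h_j \le H)$, $\sigma_{k_j,h_j,j}$ is the
minimum of $S$ over all ways of deleting $h_j$ current parents and adding
$k_j$ candidates from $V - v_j - e^-(v_j)$; added and deleted sets are
disjoint by construction (candidates exclude current parents). A cell is
infeasible — represented as `Inf`, propagated only through `min()` —
when $k_j > K$, $h_j > H$, the modified in-degree reaches $n$ or falls
below 0, or no choice exists.

The per-gene tables are mutually independent, so they are computed once
(`sigmaTable()`) and reused across all cells of the dynamic program

$$D[k', h', j+1] = \min_{k''+h''\text{ splits}}
  \big\{ D[k'-k'', h'-h'', j] + \sigma_{k'',h'',j+1} \big\},$$

whose final cell $D[k,h,n]$ is the exact optimum within the capped search
space and is invariant to gene ordering (a tested property). Split records
enable traceback of the argmin edge sets; an infeasible optimum returns
the input network unchanged with `feasible = FALSE`, never a partial
completion. Inference is the special case of the empty initial network
with $H = 0$; the benchmark convention is $K = 2$, $H = 0$ for inference
and $K = H = 2$ for completion.

**Determinism.** Among equal-error edge sets the lexicographically
smallest deleted set (by gene position), then the smallest added set, is
chosen; among equal DP splits the smallest $k''$, then $h''$. Equal errors
arise in degenerate data (e.g. duplicated genes), and fixed tie-breaking
makes every result reproducible.

**Complexity.** With caps fixed, each gene enumerates
$O(\binom{n}{K}\binom{d}{H})$ parent sets; a fit costs $O(m)$ after the
shared cross-product cache (below), giving $O(m\,n^{K+1} + n^3)$ overall.
Caps above 3 are refused without an explicit override, since the
enumeration is exponential in the cap — completion should start from
sparse, not dense, networks.

## Numerical choices

* `fitNode()` solves the design-matrix least squares by SVD with a
  relative singular-value cutoff of `1e-10`, returning the minimum-norm
  solution and a `rankDeficient` flag when columns (or replicated
  samples — e.g. exact solutions repeated verbatim) are collinear.
  Fitting must not fail on such data, merely flag it.
* The σ-table fits run off a per-dataset cache of
  $Z^\top Z$ and $Z^\top y$, where $Z$ holds the intercept, all gene
  columns and all pairwise products. Any candidate design is a column
  subset, so one fit reduces to a $p\times p$ symmetric eigensolve
  ($p \le 1+h+h(h+1)/2$) with a relative eigenvalue cutoff of `1e-12` —
  the square of a `1e-6` singular-value cutoff, matching the squared
  conditioning of normal equations. Residuals are clamped at zero against
  roundoff.
* The two routes agree to ~1e-8 relative on well-conditioned data (tested
  against `stats::lm` as an independent oracle); the cached route is what
  the DP consumes, the SVD route is the user-facing contract.

## The synthetic benchmark generator

Simulating steady-state data by ODE integration is circular here; instead
the generator builds *triangular quadratic fixed-point systems with
enumerable exact solutions*, in the style of the three-gene exemplar
$x_1 = x_1^2 - 2$, $x_2 = x_2^2 - 6$, $x_3 = x_1x_2 - 1$ (four exact
solutions; `exemplarSystem()`):

* **Sources** obey $x = x^2 - c$ with $c = r(r-1)$, so the roots are the
  integers $r$ and $1-r$, $r \in \{2,\dots,5\}$. Each source contributes a
  self-loop and doubles the solution count: $s$ sources give $2^s$
  solutions (Cartesian product of root choices), each extending uniquely
  through the triangular derived rules.
* **Derived genes** draw 1–2 lower-indexed parents and a rule that is a
  parent product, a square, or a bilinear combination with small integer
  coefficients and an integer intercept in $[-6, 6]$. Every rule carries a
  genuine quadratic term: a rule *affine* in a parent would be exactly
  invertible inside the model class, making the child an interchangeable
  surrogate for its parent.
* **Identifiability margins.** A candidate rule is accepted only if, on
  the exact solutions, (a) values stay within 30 and are non-constant,
  (b) each parent's partial derivative stays within 6 — this bounds the
  observation noise propagated through fitted coefficients to about
  $2\cdot 6^2 \sigma^2 \approx 0.5$ per sample for uniform noise with
  $\sigma^2 = 1/12$ — and (c) **no alternative parent set of up to two
  genes** other than the true parents fits the gene's values within a mean
  squared error of 2 per solution. Pairs suffice because any smaller set
  is nested in a checked pair; and pairwise coverage is exactly what
  per-gene caps of 2 can exploit. A closure check re-validates earlier
  genes against pairs involving the new gene. The margin of 2 sits well
  above the ≤ 0.5 per-sample noise-propagation differences, so on
  noisy data the true configuration wins by a statistically overwhelming
  gap at the benchmark sample sizes.
* **Feasibility.** Margins occasionally paint a draw into a corner (an
  accepted gene can make one of its parents unusable later); the
  generator then restarts the whole system from a deterministically
  derived seed, keeping it a pure function of its arguments. At least 4
  sources are required in practice: a quadratic in two genes spans 6 of
  the $2^s$ dimensions of the solution-grid function space, so an 8-point
  grid ($s=3$) leaves no room for margins. The package default is 6
  sources (64 solutions).

Solutions are perturbed into samples by adding independent uniform noise
on $[-0.5, 0.5]$ to every gene of every replicate — 400 replicates per
solution by default, with the unperturbed solutions kept as additional
samples (so 4 solutions yield 1604 samples). Replication is what
stabilises the least-squares systems; the exact solutions alone are
rank-deficient.

**What this emulates — and what it does not.** The generator reproduces
the structure the completion method assumes: low-indegree directed
regulation, polynomial steady-state relations, bounded i.i.d. noise, and
known ground truth. Real expression data violate most of this: noise is
heteroscedastic and correlated, regulation saturates rather than growing
quadratically, feedback cycles exist (the triangular systems have none
beyond source self-loops), and the true network is neither known nor
uniquely identifiable. Passing benchmarks here therefore demonstrates the
*optimisation machinery* — that the DP finds the capped optimum and that
the optimum coincides with ground truth when the data identify it — not
that the quadratic model recovers real regulatory networks.

## The modification protocol and accuracy

Benchmarks disturb a gold-standard network by `kAdd` random absent edges
and `hDel` random present edges (`modifyNetwork()`), then ask completion
to undo this. With `recoverableOnly` (the default) modifications avoid
self-loops in both directions, since the candidate rule could never re-add
a deleted self-loop. Completion accuracy is

$$\frac{h + k + |E_{org} \cap E_{cmp}| - |E_{org}|}{h + k},$$

1 when every modification is reversed, 0 when none are. Inference accuracy
is the fraction of original edges correctly inferred; directed matching is
the default for this method's output (its model is directional), while
undirected matching — an original edge credited if either orientation was
inferred, each original edge at most once — exists for parity with tools
that output undirected associations. The number of edges to add during
inference is exposed as an explicit `k` (self-loops are not addable, so
"as many edges as the gold standard" would include unreachable ones).

Even with an identifiable system, a random modification can be
unrecoverable: placing three additions on one gene cannot be reversed
under $H = 2$. At $k = h = 4$ on 10 genes this happens in a few percent of
draws and is the dominant cause of benchmark cells averaging slightly
below 1; it is a property of the random protocol, not of the search.

## Problem sizes and defaults

The shipped benchmarks use 10- and 20-gene systems with 6 sources, 400
replicates per solution (25 664 samples), $K = H = 2$, and 5 modification
seeds per cell — each cell completes in seconds on one CPU, with the
per-gene σ tables dominating the cost, as the complexity analysis
predicts. `runBenchmark()` reports per-run wall time as information only;
it is never part of any pass/fail decision.

## Known limitations

* Only the capped search space is explored: a completion needing 4
  additions at one gene is invisible at $K = 2$.
* The model class is fixed at degree 2; saturating or higher-order
  regulation is out of scope, as are regularisation and model selection.
* Budgets must be exact: the method spends all of $k$ and $h$ even when
  fewer modifications would fit better, because budget choice is the
  caller's statement of how much the initial network is distrusted.
* `allowSelfLoops = TRUE` makes every gene's self-identity fit available,
  which collapses inference toward self-loops; it exists as an escape
  hatch and is off by default.
* Time-varying networks and unbounded-indegree completion are not
  implemented.
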