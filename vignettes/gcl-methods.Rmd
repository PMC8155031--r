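---
title: "Measuring gene-to-gene coordination: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gene-to-gene coordination: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gclsim)
```

## The problem

Single-cell expression profiles vary from cell to cell for two very
different reasons: the cells' regulatory dynamics genuinely differ
(biological variability), or the measurement process adds noise
(technical variability). Pairwise summaries — the mean dissimilarity
between cells, or the average absolute gene–gene correlation — cannot
tell these apart. The global coordination level (GCL) can, because it
responds specifically to *coordination between gene sets*, which only
regulatory interactions produce.

## The statistic

For a cohort $X_{N\times M}$ (genes $\times$ cells), one GCL evaluation:

1. divide the genes at random into two complementary halves $A$ and $B$
   of $\lfloor N/2\rfloor$ genes each;
2. treat cells as samples: compute the two $M\times M$ Euclidean
   distance matrices, U-center them, and form the bias-corrected
   distance correlation
   $\mathrm{bcdCorr}(A,B) = \langle\tilde A,\tilde B\rangle /
   \sqrt{\langle\tilde A,\tilde A\rangle\langle\tilde B,\tilde B\rangle}$;
3. repeat over $m$ independent splits and average:
   $\mathrm{GCL}(X) = \frac1m\sum_k \mathrm{bcdCorr}(A^k,B^k)$.

U-centering (the $n-2$ and $(n-1)(n-2)$ denominators, zero diagonal)
makes the distance-covariance estimator unbiased, so the GCL of
independent genes is zero in expectation and can legitimately dip
negative. This matters: the naively double-centered statistic is
strictly positive at any finite sample size and would report
"coordination" everywhere (the test suite demonstrates the contrast).

**Choices within the statistic.**

* *Distance metric*: Euclidean on untransformed expression values, the
  canonical choice for distance correlation. Callers who want log or
  rank scales can transform the matrix first; ranks make the statistic
  fully monotone-invariant at some cost in sensitivity.
* *Odd $N$*: one uniformly random gene per split is left out of both
  halves, keeping the views dimensionally balanced.
* *Degenerate splits*: a view in which all cells coincide has zero
  self inner product, and tiny samples can drive it negative; such
  splits score 0 with a warning rather than propagating NaN.
* *Splits*: drawn independently, with replacement across $k$ — no
  stratification.
* *$m$*: on a fixed cohort the split-sampling noise of the GCL
  estimate declines as $\sqrt{v/m}$ (splits are i.i.d. draws), while
  the across-realization spread of the statistic does not shrink with
  $m$ at all; by $m \approx 10$ the split noise is already well below
  the realization-to-realization spread, so further splits refine the
  estimate but not the inference. The package default is $m = 50$
  throughout.

### Per-cell normalization, and why it is the default

`compute_gcl(normalize = "cell")` rescales every cell's sub-profile to
unit Euclidean norm *within each view* before distances are computed.
This choice is load-bearing. A constant-sum (compositional) cohort
acquires genuine multivariate dependence from normalization alone:
every gene in a cell is divided by the same noisy total, so when one
gene dominates the total, all other genes share a common amplitude
factor — and distance correlation, working on raw Euclidean geometry,
correctly reports that dependence (we measure GCL $\approx 0.47$ on
the $\gamma = 1.5$ compositional null with raw distances; per-gene
rank or z-score transforms make it *worse*, $\approx 0.9$, because
they amplify the shared ordering). A statistic meant to ignore
compositional artifacts must therefore be invariant to per-cell
amplitude factors. Unit-norm cells deliver exactly that invariance:
the compositional null drops to GCL $= 0.000 \pm 0.005$ while every
regulatory-network result is essentially unchanged (interacting
cohorts shift by $< 0.005$), because regulatory coordination lives in
the expression pattern, not in a shared scale.

The trade-off is explicit: a cohort whose *only* structure is a
common per-cell amplitude (every gene proportional to one cell
scalar) is, under the default, indistinguishable from depth
variation and scores 0 (with a degenerate-view warning, since each
normalized view collapses to a point). `normalize = "none"` restores
raw-amplitude sensitivity, and scores such a cohort 1 on every
split.

## Significance

`gcl_significance()` combines two resampling devices. The null model
permutes each gene's values independently across cells — gene
marginals are preserved exactly, coordination is destroyed — and the
one-sided p-value is the smoothed exceedance fraction
$(1 + \#\{\mathrm{null}\ge\mathrm{obs}\})/(n+1)$. A leave-one-cell-out
jackknife reports the observed statistic's spread. Under the null the
p-value is calibrated (the suite checks the rejection rate at level
0.05); the smoothing floor $1/(n+1)$ is the smallest attainable value.

## The cohort simulator

Each cell $\nu$ is the steady state of a saturating-activation GRN ODE

$$\dot x_i = -B\,x_i + \sum_j w^{(\nu)}_{ij}\,
  \frac{x_j^{\,n}}{1 + x_j^{\,n}},$$

with degradation $B=1$ and Hill exponent $n=1$ by default. The base
network gives every gene a self-loop and adds directed interaction
links as an Erdős–Rényi draw with average degree 2; all existing link
weights are i.i.d. $\mathcal U(0,2)$. The two variability dials are:

* **heterogeneity $p$** (biological): per cell, every existing weight —
  self-loops included — is redrawn from $\mathcal U(0,2)$ with
  probability $p$; the topology never changes;
* **noise $\sigma$** (technical): measured values are
  $\tilde x = x^*(1+\epsilon)$, $\epsilon\sim\mathcal N(0,\sigma^2)$,
  floored at 0 (the floor matters only for $\sigma$ well above the
  0–0.5 study range).

Five of the 200 genes per cell are *inoperative*: clamped to zero
during the integration, so a dead gene also stops activating its
targets (an alternative reading — zeroing the readout after solving —
is deliberately not the default, because "inoperative" describes the
gene, not the measurement). The inoperative set is drawn per cell;
`inoperative_per = "cohort"` shares one set across cells. Initial
conditions are i.i.d. $\mathcal U(0,1)$ per gene per cell.

### Numerical choices

The steady state is found by integrating with an adaptive
Dormand–Prince 5(4) scheme (compiled, per-component error control)
until $\max_i |\dot x_i| < 10^{-6}$, erroring out at $t_{\max} = 5000$.
Two tolerances deserve comment:

* *Integration accuracy*: `rtol = 1e-8`, `atol = 1e-10`. The residual
  check is only meaningful if the trajectory is more accurate than the
  threshold it certifies; at looser tolerances the numerical solution
  wanders inside its own error band around the fixed point and
  $\max|\dot x|$ stalls near $10^{-6}$ without ever crossing it.
* *Horizon*: weights near the transcritical value ($w_{ii}$ just above
  $B$, which $\mathcal U(0,2)$ produces regularly) give relaxation
  rates of order $|w_{ii}-1|$, and exactly at the threshold the decay
  is algebraic ($x\sim 2/t$). $t_{\max}=5000$ accommodates these
  genuinely slow but convergent cells.

Multistability is real in this model: different initial conditions can
reach different stable states. The simulator accepts whichever state
the trajectory reaches — that is a documented source of cell-to-cell
variability present even at $p=0$.

## Comparison metrics and the null generators

*Cell-to-cell variability* is the mean over cell pairs of one minus
the Spearman correlation of their profiles (range $[0,2]$); *average
co-expression* $\langle C\rangle$ is the mean absolute Spearman
correlation over gene pairs. Both use midranks for ties. Constant
profiles (e.g. all-zero inoperative genes) have no defined rank
correlation; their pairs score 0 with a warning (`strict = TRUE`
errors instead) so a handful of dead genes cannot poison a cohort
average.

The compositional null draws a master profile from a Pareto density
$p(x)\propto x^{-\gamma}$ on $[1,\infty)$ (inverse-CDF; the lower
cutoff is immaterial because profiles are normalized), multiplies it
per cell by i.i.d. $\mathcal N(1, 0.2^2)$ factors, and rescales every
cell to sum to one. No step couples distinct genes, so all measured
co-expression there is an artifact of the constant-sum constraint —
it grows as $\gamma\to 1$ while the GCL stays at zero.

## The simulation studies

The sweep drivers reproduce the package's three studies as tidy
tables: GCL versus $p$ with and without interactions; the full
$p\times\sigma$ factorial with iso-variability contour tracing (GCL
ordered by $\log(p/\sigma)$ along a contour); $\langle C\rangle$
versus GCL under shrinking cell counts and under compositional
normalization. Design points:

* Per-realization seeds derive deterministically from the master seed,
  so sweeps are reproducible row-by-row and the $\sigma=0$ column of
  the factorial equals the noise-free sweep under a shared seed.
* The $M$-sweep subsets *one* master cohort per realization (nested
  prefixes) rather than resimulating per $M$: this isolates the
  sample-size effect from realization noise.
* Contour extraction finds the linear level crossings on the grid-cell
  edges directly and interpolates the GCL bilinearly at those points;
  interpolated variability equals the requested level to $10^{-6}$ by
  construction. Points on the $\sigma = 0$ boundary are dropped
  (log-ratio undefined).
* The test suite runs the factorial at a reduced scale (N = 100 genes,
  M = 50 cells, $5\times5$ grid, 5 realizations) and the remaining
  studies at their reference sizes with 10–20 realizations; the full
  420-cohort factorial ($20\times21$ grid at $N=200$, $M=100$, 20
  realizations) is available through the same driver.

## What the generator does and does not emulate

The simulator produces smooth, $O(1)$-scale steady-state expressions
with controllable regulatory heterogeneity and Gaussian multiplicative
noise. It does **not** emulate count noise, dropout, library-size
variation, repression, stochastic (Langevin/Gillespie) dynamics, or
cell sub-populations. Passing tests therefore demonstrate the
statistic's behavior under cleanly separated biological/technical
variability — not robustness to every artifact of real scRNA-seq data,
for which the quality filters (`remove_outlier_cells()`,
`remove_near_duplicate_cells()`) and upstream sub-population selection
remain necessary.

## Known limitations

* The GCL is a global statistic: it detects that coordination exists,
  not which genes carry it.
* Jackknife + permutation significance costs $(M + n_{\mathrm{resample}})$
  GCL evaluations; for large cohorts reduce `m` or disable the
  jackknife.
* The outlier filter is single-pass by definition; re-applying it can
  remove more cells. The near-duplicate filter is idempotent in
  practice but its threshold is relative to the median pairwise
  distance, which shifts slightly after removals.
* Negative bcdCorr values are expected noise around zero, not evidence
  of "anti-coordination".
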