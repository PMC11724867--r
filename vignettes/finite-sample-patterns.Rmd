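---
title: "Finite-sample lattice patterns in mean–Fano factor plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-sample lattice patterns in mean–Fano factor plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanolattice)
```

## The phenomenon

A mean–Fano factor plot summarises a single-cell transcript count matrix
one gene at a time: the x-coordinate is the gene's mean count across
cells, the y-coordinate its Fano factor (variance over mean; 1 for
Poisson, above 1 for bursty super-Poisson expression, below 1 for
sub-Poisson). When the plot is restricted to weakly expressed genes
(mean below about 1) and the sample comprises the few tens to few
hundreds of cells typical of high-quality single-cell data, the points
do not scatter: they arrange themselves onto a family of smooth curves,
with a strikingly regular vertical spacing between neighbouring points
on the same curve, and an empty triangle in the lower-left corner.

These patterns are not biology and not a measurement artifact. They are
a finite-sample counting effect, and this package implements the exact
theory of them.

## The model

Let $n_c$ be the number of cells and write $T = \sum_j n_j$ and
$S = \sum_j n_j^2$ for a gene's integer count vector
$(n_1,\dots,n_{n_c})$. With population moments (divisor $n_c$),

$$\langle n\rangle = T/n_c, \qquad
\mathrm{FF} = \frac{\langle n^2\rangle - \langle n\rangle^2}{\langle n\rangle}
            = \frac{n_c S - T^2}{n_c T}.$$

**Curve $k$.** Suppose a gene's counts are all 0 or 1 except for exactly
$k$ cells with 2 transcripts. Eliminating the fraction of 1-cells from
the two moments gives

$$\mathrm{FF} = 1 - \langle n\rangle + \frac{2k}{n_c\,\langle n\rangle},$$

a one-parameter family of curves indexed by the integer $k$. Curve 0 is
the straight Bernoulli line $\mathrm{FF} = 1 - \langle n\rangle$; for
$k \ge 1$, solving for the mean gives

$$\langle n\rangle = \tfrac12\left(1 - \mathrm{FF} +
  \sqrt{\frac{8k + n_c(\mathrm{FF}-1)^2}{n_c}}\right).$$

At low expression almost every gene has counts $\le 2$, which is why the
observed plots decompose into Curves 0, 1, 2, ... (`curve_ff()`,
`curve_mean()`, `assign_curves()`).

**General counts.** If $m_i$ cells have exactly $i \ge 2$ transcripts,
the same elimination yields

$$\mathrm{FF} = 1 - \langle n\rangle +
 \frac{\sum_{i\ge2} i(i-1)\,m_i}{n_c\,\langle n\rangle},$$

which is the simple formula with the *effective index*
$k_\mathrm{eff} = \sum_{i\ge2}\binom{i}{2} m_i$. Algebraically
$k_\mathrm{eff} = (S-T)/2$, always an integer because $n^2 \equiv n
\pmod 2$; the identity holds for **every** integer count vector, not
only for the 0/1/2 case, and is what `general_ff()` computes and the
test suite verifies exhaustively.

**The lattice.** $T$ is an integer, so a gene's mean can only take the
values $i/n_c$. On Curve $k$ the admissible numerators run from
$\max(2k, 1)$ to $n_c + k$ (the non-2 cells contribute between 0 and 1
each). The attainable $(\langle n\rangle, \mathrm{FF})$ pairs therefore
form a discrete lattice (`predict_lattice()`), and the vertical spacing
between successive occupied points on a curve is an exact integer
multiple of $1/n_c$ — one lattice step when adjacent points are both
realized, two when the gene between them is missing (undetected through
imperfect capture, or simply absent). `delta_y()` reports these steps
in $1/n_c$ units together with the fraction equal to one unit.

**The empty triangle.** For any discrete count distribution,
$\langle n^2\rangle \ge \langle n\rangle$, hence
$\langle n\rangle \ge 1 - \mathrm{FF}$ with equality exactly for
0/1-valued (Bernoulli) data. Nothing can fall below Curve 0
(`min_mean_bound()`).

## Exact arithmetic as a design requirement

Every claim above is an exact statement about integers: "the mean is a
multiple of $1/n_c$", "the point coincides with the predicted lattice
point". Verifying them through floating point would replace identities
with tolerances and silently weaken the strongest available check (an
exact mismatch signals a bug, full stop). The package therefore runs
all curve, lattice and spacing logic on an internal exact rational
vector class (`rational()`): integer numerators and denominators stored
in doubles, reduced by GCD, with every operation guarded to stay below
$2^{53}$ where double-held integers are exact (an overflow aborts
rather than rounding — unreachable in practice, since the largest
intermediates scale like $n_c \cdot S$). Doubles appear only at
presentation boundaries (plot columns, CSV exports) and in the one
place the mathematics itself is irrational: the square root in the
Curve-$k$ inversion, where only the positive root is a positive mean
and round-tripping is accurate to better than $10^{-12}$ relative
(measured: $\sim 5\times10^{-15}$ over every feasible lattice mean for
$k \le 20$, $n_c \in \{50, 101, 500\}$).

Other numerical and policy choices:

* **Population moments.** The divisor is $n_c$, not $n_c - 1$; the
  curve identities are exact only in that convention. A conventional
  sample variance is available via
  `gene_moments(x, sample_variance = TRUE)` and is never used by the
  curve logic.
* **Unexpressed genes.** The Fano factor is undefined at mean 0; genes
  with $T = 0$ carry `NA`, are flagged, counted in the log output, and
  excluded from all curve analyses.
* **Duplicate coordinates.** Distinct genes sharing an exact
  $(\langle n\rangle, \mathrm{FF})$ point collapse to one point for
  spacing analysis; multiplicity is retained in the lattice-match
  report's gene lists.
* **Curve membership is a count signature, never clustering.** A gene is
  on Curve $k$ because it has $k$ cells at two transcripts — a
  deterministic, exact criterion — not because it lies near a curve in
  the plot.
* **Window defaults.** `mean_max = 1` and `k_max = 2`: the patterns
  live in the weakly expressed region, and the three lowest curves are
  the ones that stay visually separated; both are arguments everywhere.
* **Indices above $n_c$.** At most $n_c$ cells can hold two
  transcripts, so enumeration functions (`feasible_mean_range()`,
  `predict_lattice()`) cap $k \le n_c$; `curve_ff()` itself accepts any
  non-negative $k$ because effective indices of genes with counts above
  2 legitimately exceed $n_c$ (a single count of 5 contributes
  $\binom{5}{2} = 10$).

## What the generator emulates — and what it does not

`simulate_counts()` produces gene × cell matrices with the statistical
structure the theory assumes: i.i.d. integer counts per gene across
cells, drawn from

* **bernoulli** — detection-limited 0/1 data (Curve 0 by construction);
* **poisson** — constitutive expression (log-uniform mean in
  $[0.005, 1]$ by default);
* **negative_binomial** — bursty expression parameterised directly by
  (mean, Fano) with burst size $\mathrm{FF} - 1$, the parameterisation
  the mean–Fano plane makes natural (defaults: log-uniform mean in
  $[0.005, 1]$, uniform Fano in $(1, 4]$); internally
  `size = mean / (fano - 1)`;
* **telegraph** — a two-state promoter's steady state sampled as a
  Poisson–Beta mixture: counts $\sim$ Poisson(burst_size · koff · B)
  with $B \sim \mathrm{Beta}(\text{burst\_freq}, \text{koff})$, the
  off-rate fixed at 10 and (burst_freq, burst_size) exposed as ranges
  (defaults $[0.05, 0.5]$ and $[0.5, 3]$, keeping means mostly below
  1);
* **custom_pmf** — an arbitrary finite discrete distribution, which
  makes the mechanism-independence point: the patterns need integers,
  not any particular law, and apply just as well to non-transcriptomic
  count data.

Two measurement-process layers can be added: **binomial capture
thinning** (`apply_capture()`, each transcript kept independently with
the capture efficiency — the standard model of partial transcriptome
capture) and **extrinsic noise** (a per-cell log-normal factor with
unit mean and configurable CV multiplying each cell's mean before
sampling; log-normal is the conventional choice for cell-size-like
variation, and any positive unit-mean law leaves every tested invariant
intact). Default sample sizes follow the regime where the patterns are
prominent: $n_c = 101$ cells in the simulation-based checks, a few
thousand genes.

Reproducibility: one seed expands into per-gene substreams (so growing
`n_genes` never reshuffles existing genes) and thinning streams are
keyed by gene identifier (so thinning commutes with subsetting genes).

The generator deliberately does **not** model UMI collisions or
sequencing errors, doublets, ambient RNA, zero-inflation mechanisms, or
time-course promoter dynamics. Counts are i.i.d. across cells given the
extrinsic factor; real data have cell-type structure and gene–gene
correlation. None of that weakens what the passing tests establish —
the lattice, spacing and bound results are distribution-free statements
about integer matrices, so they hold for real count data a fortiori —
but parameter-level realism (e.g. which lattice points are occupied,
the observed fraction of unit steps) is only as real as the chosen
parameter ranges.

## Problem sizes used in the checks

The test suite enumerates all ~1,100 count vectors with $n_c \le 6$ and
entries $\le 2$ (plus entries $\le 3$ for the bound's equality
condition), checks the general theory on ~10,000 random vectors with
$n_c \le 12$ and entries $\le 5$, and runs simulation-based checks at
5,000 negative-binomial genes and 1,500 genes per alternative family at
$n_c = 101$, with capture efficiency 0.1 and extrinsic CV 0.5 as the
stressed variants. These sizes make every exhaustive claim genuinely
exhaustive in its stated window while keeping a full run in the order
of a minute.

## Known limitations

* Exact rationals use double-held integers: valid below $2^{53}$,
  enforced by an explicit guard. Data needing larger intermediates
  (e.g. $n_c \cdot S \ge 2^{53}$) would abort rather than lose
  precision; no realistic single-cell matrix is close.
* `curve_mean()` is float-based (the square root); exact statements are
  always phrased through `curve_ff()` on rational means.
* The lattice-match window (`mean_max`, `k_max`) bounds the report, not
  the theory; genes outside it are simply not reported.
* Dense input read in strict mode insists on integer literals; files
  that went through a float round trip need `permissive = TRUE` (values
  must still be exactly integral).
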