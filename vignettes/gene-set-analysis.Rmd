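---
title: "Self-contained gene set analysis with msgsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-contained gene set analysis with msgsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msgsa)
```

## The problem and the hypothesis being tested

Expression studies routinely ask whether a *predefined* set of genes — a
pathway, a curated signature — responds to an experimental condition, rather
than whether any single gene does. Two nulls are in circulation. The
*competitive* null compares a set against the other genes on the array and is
resampled by permuting genes, which makes the resampled statistics mutually
dependent. The *self-contained* null states that **no gene in the set is
associated with the phenotype** and is resampled by permuting samples
(subjects), which respects the independence structure of the data. This
package implements the self-contained approach only: every set-level P-value
here is a subject-permutation P-value.

Three families of statistics are offered, because gene sets fail the null in
different ways:

1. **One-sided OLS global statistic** (two conditions). Genes are
   standardized as $y^*_{ijk} = (y_{ijk} - \bar y_k)/s_k$, with $\bar y_k$
   the grand mean and $s_k$ the pooled within-group standard deviation
   (divisor $N - c$). With $\mathbf d$ the vector of per-gene differences of
   group means of $y^*$, the statistic is
   $T_{\mathrm{ols}} = \mathbf 1'\mathbf d / (\mathbf 1' V \mathbf 1)^{1/2}$,
   $V = S_{\mathrm{pooled}}(1/n_1 + 1/n_2)$. It is powerful when the genes
   move *coordinately in one direction*, and its sign reports that direction
   (positive = higher in the first condition).
2. **Hotelling's $T^2$ / Wilks' $\Lambda$ MANOVA** (two or more conditions).
   Two-sided, multivariate; sensitive to changes in any direction. With $H$
   the between-group SSP matrix and $E = (N - c)\,\hat\Sigma$,
   $\Lambda = \prod_k (1 + \lambda_k)^{-1}$ over the $\min(m, c-1)$
   eigenvalues of $E^{-1}H$, equivalently $\det E / \det(E + H)$. At $c = 2$
   the classical identity $(N-2)(1-\Lambda)/\Lambda = T^2$ holds exactly, and
   the test suite enforces it to $10^{-10}$ relative tolerance.
3. **Random-forests OOB test** (categorical *or continuous* phenotype). The
   set is scored by how well a forest on its genes predicts the phenotype:
   the out-of-bag misclassification rate (classification) or out-of-bag mean
   squared error (regression). The P-value is
   $\sum_k \mathbf 1\{R^{(k)} \le R_0\}/N$ over $N$ phenotype permutations,
   each with a freshly grown forest; ties count as extreme. Because it is
   tree-based, it also picks up monotone-nonlinear association.

## Why a shrinkage covariance, and which one

Gene sets frequently contain more genes than there are samples, so the
pooled sample covariance is singular and $T^2$/$\Lambda$ are undefined. We
therefore estimate the covariance by shrinking the sample *correlation*
matrix toward the identity,
$r^*_{ij} = r_{ij}\min\{1, \max(0, 1 - \hat\lambda^*)\}$, with the
data-driven intensity
$\hat\lambda^* = \sum_{i\ne j}\widehat{\mathrm{Var}}(r_{ij}) \big/ \sum_{i\ne j} r_{ij}^2$
and $\widehat{\mathrm{Var}}(r_{ij}) = \frac{n}{(n-1)^3}\sum_k (w_{kij} -
\bar w_{ij})^2$ computed from the standardized products
$w_{kij} = \tilde x_{ki}\tilde x_{kj}$. Variances stay untouched on the
diagonal. For multi-group tests the inputs are within-group residuals and
all divisors become $n - g$. Two numerical conventions are worth stating:

* when every off-diagonal correlation is exactly zero the intensity is
  defined as $+\infty$ (full shrinkage, diagonal covariance), avoiding a
  0/0;
* correlations below $10^{-12}$ in magnitude are treated as zero — they are
  BLAS rounding residue, not signal, and would otherwise destabilise the
  0/0 rule above.

Shrinkage is applied *unconditionally*, not only when $m > N$. A single code
path means the permutation null and the observed statistic are always
computed under the same estimator, which is what makes the permutation
P-value exact regardless of how aggressive the shrinkage is. For
$\hat\lambda^* \in (0,1)$ the shrunk correlation matrix
$(1-\hat\lambda^*)R + \hat\lambda^* I$ is positive definite, so the
statistic always exists.

## P-value conventions and multiplicity

Permutation P-values are plain counts, $\#\{\text{at least as extreme}\}/
\texttt{nperm}$, with no +1 correction — a set more extreme than every
permuted draw reports $P = 0$. Users who need strictly positive P-values
(e.g. for downstream log-transforms) can switch to
$(1 + \#)/(1 + \texttt{nperm})$ via `plus_one = TRUE`. The OLS test reports
the caller's chosen tail only (default upper = upregulation in the first
condition), never a doubled or min-of-both-tails value; the direction is
readable off the statistic's sign either way.

Across sets, each test family gets two adjustments:

* **BH-FDR step-up**: $\tilde p_{(r)} = \min_{j \ge r} p_{(j)} m/j$. The
  implementation accepts a family size `m_total` larger than the number of
  P-values supplied, so the adjustment can be reproduced for published
  tables that print only the top of a large family.
* **Permutation FWER**: single-step Westfall–Young. The default is min-P
  (each permutation row is converted to per-set empirical P-values, row
  minima form the reference distribution); max-T is available where the
  statistics share a scale. Single-step rather than step-down was chosen
  deliberately: single-step adjusted values need not be monotone in the raw
  P-value ordering — a behaviour observed in published FWE columns of this
  kind of analysis — and it composes exactly with the shared permutation
  stream. Both procedures operate on ranks, so they are invariant under
  monotone transformations of the statistic.

One permutation stream, keyed by `seed`, is reused across all sets and both
statistics of a family. That coupling is not an optimisation: the min-P/max-T
adjustment is only valid if all family members see the *same* resampled
subjects.

## Post hoc comparisons among three or more conditions

When the MANOVA rejects, three pair-selection schemes localise the signal:
Dunnett (every condition vs the first-appearing, reference condition), Tukey
(all pairs), and sequential (each condition vs its predecessor, for ordered
conditions). The literature usually attaches parametric critical values to
these names; here they are realised as *pair-selection schemes over
permutation-based pairwise Hotelling tests*, with single-step max-T family
adjustment, because every other P-value in the package is permutation-based
and mixing parametric and permutation families would make the columns
incomparable. Pairwise permutations shuffle labels only within the two
groups compared — the pairwise null concerns those two groups alone. Each
pair's permutation substream is keyed by the pair's identity, so a pair
shared between schemes (a Dunnett pair inside the Tukey family) sees
identical null draws and its adjusted P can only grow as the family grows.

## Gene-level reporting and the plots

Per-gene statistics (pooled-variance $t$ at $c=2$, one-way $F$ otherwise)
are parametric, two-sided, and feed two places only: the per-gene table for
significant sets, and the shading of the ranked-statistic (GST) plot at a
default $\alpha = 0.01$. The GSA plot draws each family's ordered P-values
against rank/$k$; under a global null this is a diagonal, and truly
associated sets pull its left end down. Both plots are computed as arrays
first (`gsa_plot_data()`, `gst_plot_data()`) and rendered second, so tests
assert on numbers, never pixels.

## The simulation harness: what it emulates, what it does not

`sim_scenario()` encodes the synthetic-data design the package is calibrated
against: $n \in \{10, 20, 50\}$ samples over gene sets of size
$p \in \{20, 100, 200\}$, per-gene means drawn from $U(0, 10)$, variances
from $U(1, 5)$, and a mixed correlation structure — a compound-symmetry
block of $p_1$ genes at correlation $\rho$, an AR(1) block of the next $p_1$
genes at $\rho^{|i-j|}$, independence elsewhere, $\rho \in [0, 0.9]$. A
continuous phenotype is $Y = X\mu + \varepsilon$ (linear) or
$Y = \exp(X\mu) + \varepsilon$ (nonlinear), $\varepsilon \sim N(0, I)$.
Under the alternative, $\mu$ has exactly five nonzero entries among genes
1–20 drawn from $N(\nu, |\nu|)$ and five among genes 21–40 from
$N(-\nu, |\nu|)$ — ten associated genes out of $p$.

Two ambiguities in this design were resolved as follows and are flagged
here because they matter quantitatively:

* $N(\nu, |\nu|)$ is read as **mean $\nu$, standard deviation $|\nu|$**. At
  $\nu = 0.2$ the SD-vs-variance reading changes the spread of the effect
  sizes by a factor of $\sqrt 5$, which shifts power curves materially; the
  SD reading is the common notation in this literature and keeps the
  $\nu = 0$ null degenerate at exactly zero.
* Everything — gene means, variances, effect positions and values, and the
  expression matrix — is **redrawn each replicate**. A fixed-$X$ design
  would estimate the conditional rather than the marginal rejection rate.

The generator emulates the correlation structure and effect sparsity of a
single gene set; it does *not* emulate inter-set overlap, heavy-tailed or
count-distributed intensities, technical batch structure, or
phenotype-dependent variance. Calibration results under this generator
therefore demonstrate correctness of the permutation machinery, not
robustness to everything real data can do.

Problem sizes used by the shipped checks: null calibration runs 200
replicates x 200 permutations x 100 trees per scenario and compares the
empirical rejection rate within three binomial standard errors of the
reference rates; the power-ordering check uses 60 replicates x 100
permutations x 250 trees at $n = 20$, $p = 100$ — forest noise itself
blunts the regression test at small tree counts, so the power comparison
invests in trees rather than permutations. These sizes were chosen so the whole
verification cycle completes on a laptop in well under half an hour while
keeping the binomial error bands tight enough to detect a broken test.
The structure-recovery check uses $n = 50{,}000$ draws, where the sampling
error of a correlation ($\approx 0.005$) sits comfortably inside the
$\pm 0.02$ acceptance band.

## Degenerate inputs and numerical choices

* Genes with zero pooled (or overall) variance cannot be standardized and
  are dropped with a warning before testing; sets thereby reduced below two
  genes are dropped too — a set must be multivariate to be a set.
* Sets of size one are rejected at construction for the same reason.
* Gene-set membership read from GMT is matched case-sensitively; silent
  case-folding hides identifier errors.
* Permutations are drawn with replacement from the permutation group
  (uniqueness is not enforced, the identity is not excluded): at
  `nperm >= 1000` the effect on a P-value is below its Monte-Carlo noise.
* Group order is the order of first appearance in the sample row, and the
  first group is the Dunnett reference; permuted label vectors inherit the
  observed ordering so that the sign of $T_{\mathrm{ols}}$ is stable under
  resampling.
* `mtry` defaults follow the usual random-forests conventions
  ($\lfloor\sqrt m\rfloor$ classification, $\max(1, \lfloor m/3\rfloor)$
  regression); regression importance is reported as the *increase* in OOB
  MSE under out-of-bag permutation of the gene (unscaled), which is the
  quantity that is large for informative genes.

## Known limitations

* Only the self-contained null is implemented; there is no competitive
  (gene-sampling) mode.
* Set-level P-values are permutation-only; no $t$/Wilks distributional
  P-values are offered for the set tests.
* The post hoc Dunnett/Tukey realisations are permutation-based, not the
  classical parametric procedures, and will not numerically match
  parametric implementations.
* P-values of published case studies that depend on a particular legacy
  RNG and full-size datasets are not reproduced here; the package's
  correctness claims rest on the exact identities, enumeration oracles, and
  calibration bands exercised in the test suite.
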