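---
title: "Methods: regularized kernel CCA in rkcca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regularized kernel CCA in rkcca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(rkcca.verbose = FALSE)
```

## The model

Canonical correlation analysis treats two or more datasets observed over
the same samples as noisy views of shared latent structure. For
column-centered $X \in \mathbb{R}^{n\times m}$ and
$Y \in \mathbb{R}^{n\times p}$, it seeks weights $a, b$ maximizing

$$\rho \;=\; \frac{a' C_{XY}\, b}{\sqrt{(a' C_{XX}\, a)\,(b' C_{YY}\, b)}},$$

with $C_{XY} = X'Y$ etc. Rather than extracting components one at a time
under orthogonality constraints (slow, and awkward for more than two
datasets), `rkcca` solves the equivalent generalized eigenvalue problem:
the left-hand side stacks the cross-product blocks off a zero diagonal,
the right-hand side is block-diagonal in the autocovariances, and each
eigenvector splits row-wise into one weight segment per dataset. Any
number of datasets fits this layout. Regularization adds $\lambda I$ to
every diagonal block: it makes the problem solvable when a dataset has
more features than samples, shrinks the weights, and gradually relaxes the
within-set orthogonality of the components. As $\lambda \to \infty$ the
autocovariances are dominated by $\lambda I$ and the first weight pair
converges in direction to the leading singular vectors of $C_{XY}$ — the
partial-least-squares solution. This limit is verified in the test suite
rather than exposed as a separate fitter.

Two conventions matter for interpreting $\lambda$:

* **Cross-products are raw.** Neither $1/n$ nor $1/(n-1)$ scaling is
  applied, so autocovariance diagonals grow with the sample count and a
  "large" $\lambda$ must be judged against $n \cdot \mathrm{Var}$. This
  keeps grids such as $\{0, 10^2, 10^4, 10^6\}$ at $n = 500$ meaningful:
  $10^2$ is a mild ridge there, $10^6$ is effectively the PLS limit.
* **Canonical correlations for more than two datasets** are defined in
  this package as the mean over all dataset pairs of the per-component
  Pearson correlations. This is a documented contract of `rkcca`, chosen
  for symmetry; the two-dataset case reduces to the ordinary pairwise
  correlation.

## Kernel (dual) mode

For wide data ($m \gg n$) or nonlinear structure, the same block
eigensystem is assembled from Gram matrices $K = \phi(X)\phi(X)'$ instead
of covariances: off-diagonal blocks $K_X K_Y$, diagonal blocks
$K_X^2 + \lambda I$. Three kernels are provided:

| kernel   | formula                                     | parameters (default)   |
|----------|---------------------------------------------|------------------------|
| linear   | $x_i \cdot x_j$                             | —                      |
| gaussian | $\exp(-\lVert x_i-x_j\rVert^2 / 2\sigma^2)$ | `gausigma` $\sigma$ (1)|
| poly     | $(x_i \cdot x_j)^d$, homogeneous, no offset | `degree` $d$ (2)       |

Conventions, stated because alternatives exist in the literature: the
Gaussian width enters as $2\sigma^2$ in the denominator; the polynomial
kernel has no additive constant; Grams are *not* double-centered (data are
column-centered in feature space before kernel evaluation, which differs
from Gram centering for nonlinear kernels) and *not* trace-normalized, for
the same $\lambda$-scale reason as above. Dual solutions $\alpha$ are
converted to feature-space weights $w = X'\alpha$ immediately after the
eigensolve, so components, prediction and persistence are uniform across
modes. With an invertible kernel and $\lambda = 0$ the dual problem admits
a trivial solution; `fit_cca()` warns in that configuration.

## Numerical choices

* **Solver route.** Both sides are explicitly symmetrized (averaged with
  their transposes). The right-hand side $B$ is eigendecomposed,
  directions with eigenvalue below $10^{-12}$ of the largest are dropped
  (they carry no data variance — this is what makes the rank-deficient
  dual case solvable), and the whitened operator is passed to a standard
  symmetric eigensolver. Eigenpairs are sorted by descending eigenvalue;
  for two datasets the spectrum is symmetric about zero and the kept
  leading branch is the non-negative one.
* **Ridge at $\lambda = 0$.** A jitter of $10^{-8}$ times the mean
  diagonal of $B$ is added purely for numerical solvability, with a status
  message. It is orders of magnitude below data scale; unregularized
  results (e.g. the benchmark's 0.95/0.95/0.10/0.00 spectrum) are
  unaffected at reported precision.
* **Sign convention.** Each eigenvector is flipped, if needed, so the
  largest-magnitude entry of its first-dataset segment is positive.
  Canonical weights are inherently sign-ambiguous; tests compare
  magnitudes or subspaces, never raw signs.
* **Ties.** Equal eigenvalues keep the solver's stable order; nothing
  downstream depends on ordering within a tie.
* **Pseudoinverse.** `regularized_pinv()` zeroes singular values below
  `cutoff` times the largest (relative thresholding is scale-free; the
  absolute variant would not survive rescaling of the data). `cutoff = 0`
  retains everything above machine-precision scale, i.e. the plain
  Moore–Penrose inverse.
* **Degenerate inputs.** Zero-variance columns or components yield
  correlations / explained-variance rows of 0 with a warning rather than
  `NaN`; an all-zero matrix pseudoinverts to zero by convention;
  correlations of exactly $\pm 1$ are clamped to $1 - 10^{-15}$ in
  magnitude before the Fisher transform.

## Cross-dataset prediction and evaluation

To predict held-out samples of dataset $i$, every other dataset $j$ is
centered with its *training* means, projected as $U_j = \tilde X_j W_j$,
the projections are averaged (the unweighted mean is the symmetric choice;
for two datasets it is just the other view), and the average is mapped
back through the pseudoinverse of $W_i'$. Centering held-out data with
training rather than test means keeps prediction honestly out-of-sample;
per-feature accuracy is the Pearson correlation of predicted and actual
columns, which is shift-invariant, so this choice affects the absolute
scale of the predictions but not the reported correlations.

Explained variance attributes held-out structure to single components:
`ev[k, f]` is the squared correlation between component $k$'s held-out
timeseries and feature $f$ — identically the $R^2$ of the best rank-1
linear fit, verified against a residual-variance oracle in the tests.

Significance of prediction correlations uses the asymptotic Fisher-z test
($z = \mathrm{atanh}(r)\sqrt{n-3}$, two-sided normal tail) with
Benjamini–Hochberg step-up control at level $\alpha$. The underlying
asymptotic test is a package contract (the natural default for
correlations); the step-up mask is computed with `stats::p.adjust` and
checked in the tests against the procedure written out by hand.

## Hyperparameter selection

`grid_search()` scores every `(reg, numCC)` candidate with Monte-Carlo
block cross-validation: each iteration holds out
$\lfloor 0.2\,n / 10 \rfloor$ disjoint blocks of 10 *consecutive* samples
(starts aligned to multiples of the block length, drawn without
replacement — contiguous blocks respect temporal autocorrelation, and
aligned starts make splits trivially reproducible), fits on the remainder,
predicts the held-out blocks across datasets, and records the **select
metric**: per dataset, the mean of the top `select` fraction
(default 0.2, i.e. $\lceil 0.2\,p\rceil$ dimensions) of per-feature
prediction correlations, averaged across datasets. The fraction is taken
over feature *dimensions* — prediction accuracy is defined per dimension —
which keeps the score informative when many dimensions are noise. Scores
are averaged over `numCV` iterations (default 10; more iterations reduce
grid-score variance), the argmax is selected with ties broken toward
fewer components and then larger regularization (parsimony first,
shrinkage second), and the final model is refitted on all supplied data.
A candidate that cannot be fitted (e.g. `numCC` above a feature count)
scores $-\infty$ with a warning instead of aborting the search. Defaults
(`regs` = 10 log-spaced values in $[10^{-3}, 10]$, `numCCs` = 5–10) suit
covariance-scale data; for raw-cross-product fits at $n$ in the hundreds,
coarser grids like $\{0, 10^2, 10^4, 10^6\}$ are more informative.

## The synthetic benchmark

`simulate_latent_data()` draws $L$ independent standard-normal latent
variables and builds each dataset column as
`signal_weight * latent + noise_weight * noise` with fresh standard-normal
noise, from one seeded stream in a fixed order (latents first, then one
noise matrix per dataset) so a seed fully determines the output. Defaults
encode the two-dataset benchmark: $n = 1000$, weights 0.75/0.25, patterns
(L1, L2, L1, L2) and (L1, L2, L1, L2, L1). Two columns sharing a latent
then correlate at $0.75^2/(0.75^2+0.25^2) = 0.9$; the optimal
cross-dataset combination averages the per-view noise, giving population
canonical correlations of about 0.95 for the two latent components. The
latents are drawn independently but are *not* orthogonalized: their
sample correlation is $O(1/\sqrt{n})$, which is exactly why a little
regularization (which relaxes component orthogonality) tends to win model
selection on these data. Where repetitions are involved, each repetition
redraws latents *and* noise.

What the generator does **not** emulate: temporal autocorrelation,
hemodynamic dynamics, spatial structure, heavy tails, or unequal noise
across features. Passing the benchmark therefore demonstrates correctness
of the estimator and selection machinery, not robustness to the full
phenomenology of real recordings; the block-holdout CV scheme in
particular only becomes materially different from i.i.d. holdout on
autocorrelated data, which these are not.

## Problem sizes used in validation

The packaged checks run the benchmark at its native size ($n = 1000$,
split in halves): 50–60 replicate fits for the fixed-hyperparameter
spectrum and prediction quantities, and 200 replicate grid searches
($4\times4$ grid, 10 CV iterations each) for the selection-rate and
refit-quality quantities — enough replication that the Monte-Carlo error
of the reported means is well inside the stated tolerances, at a few
minutes of single-core runtime. Property checks (Pearson equivalence in
1-D, primal/dual agreement, the PLS limit, pseudoinverse and explained
variance oracles, BH step-up, persistence round trips) run at small $n$
where brute-force oracles are exact.

## Limitations

* Primal mode forms $p \times p$ cross-products; beyond a few thousand
  features per dataset, use the linear-kernel dual route instead.
* No sparse CCA, no deflation-based estimation, no Nyström or low-rank
  kernel approximations, no precomputed-kernel input.
* The spectral-cutoff pseudoinverse is the only regularization offered at
  prediction time (no L2-penalized inverse).
* Model archives are versioned and refused on mismatch; there is no
  migration of old formats.
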