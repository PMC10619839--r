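---
title: "Kernel association testing for spatially variable genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel association testing for spatially variable genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smashsvg)
```

## The testing problem

A spatially variable gene (SVG) is a gene whose expression across a tissue
section covaries with the spatial positions of the cells or spots that
express it. Given a genes × locations expression matrix `Y` and an N × d
coordinate matrix `S`, we test, gene by gene, the null hypothesis that the
expression vector `y` is independent of `S`.

The test is non-parametric and kernel-based. Dependence is measured by the
alignment of two Gram matrices: the rank-one expression Gram matrix
`E = y (y'y)^-1 y'` and a spatial kernel covariance matrix `K` built from
pairwise relations among the locations,

    T = tr(E K) / N = y' K y / (N y'y).

Large `T` means the expression profile is aligned with the leading spatial
structure encoded by `K`. Because `E` is rank one, the trace collapses to a
single quadratic form and `E` is never materialized; testing all genes
against one kernel costs `O(N^2 K)`.

No distributional assumptions are placed on `y`. The price of that
generality is that the test can only see dependence that some kernel in the
family expresses, which is why the kernel family and its hyperparameter
grids matter more than anything else in this package.

## Kernel families

Three families are implemented (`gaussian_kernel()`, `cosine_kernel()`,
`projection_kernel()`):

* **Gaussian (squared-exponential)**: entries `exp(-d_ij^2 / (2 l^2))`.
  The lengthscale `l` (same units as the coordinates) sets how fast spatial
  correlation decays; small `l` probes short-range covariance, large `l`
  smooth tissue-scale gradients.
* **Cosine (periodic)**: entries `cos(2 pi d_ij / p)` with period `p` in
  coordinate units. This family detects oscillatory expression (layered or
  banded tissue). It is sharply frequency-selective: a kernel whose period
  is even a few percent off the data's dominant wavelength can have close
  to zero, or even negative, alignment with the signal covariance. It is
  also indefinite (not positive semidefinite).
* **Linear projection**: the hat matrix of the regression of `y` on the
  column-centered (optionally Gaussian- or cosine-transformed)
  coordinates. This reproduces the SPARK-X score test exactly and detects
  first-order (mean-level) spatial trends only.

### Hyperparameter grids

For the Gaussian and cosine families, ten data-driven values of `l` and `p`
are used (`default_lengthscales()`, `default_periods()`): logarithmically
spaced from the **median nearest-neighbor distance** up to the **97.5th
percentile of the pairwise distances**. The lower end is the sampling
resolution — the shortest scale at which covariance between distinct
locations is observable at all — and the upper end is the tissue extent.
We anchor the grid at the resolution rather than at a percentile of the
pairwise-distance distribution because the latter scales with the window
(≈ 9% of the side length for a uniform point pattern) regardless of how
densely the tissue is sampled, and therefore can never reach sub-unit
wavelengths on a multi-unit tissue; short-period oscillations would then be
invisible to every kernel in the family. With the resolution-to-extent
span, dense data automatically buy access to finer spatial scales. For
N > 2000 the distances are computed on a deterministic random subsample of
2000 locations (seeded; `O(N^2)` memory stays bounded).

The projection family uses seven kernels: the identity transform plus
Gaussian- and cosine-transformed coordinates at three per-dimension scales,
the {25, 50, 75}% quantiles of the centered absolute coordinates. These
quantile scales are stand-ins for choices the reference methods leave
unspecified; they are data-driven and scale-equivariant.

## Null distribution

Under independence, the quadratic-form statistic follows asymptotically a
weighted mixture of chi-square(1) variables, the weights being products of
the eigenvalues of `E` and `K`. Eigendecomposing `K` costs `O(N^3)`, so the
mixture is approximated by moment matching (Welch–Satterthwaite) with a
gamma distribution:

    E(T) = tr(K) / N^2,   V(T) = 2 tr(K^2) / N^4,
    shape = E^2 / V,      scale = V / E,

with `tr(K^2)` computed as the sum of squared entries (`O(N^2)`, no
eigendecomposition).

**Which kernel do the traces come from?** Expression vectors are always
residualized against the covariate design `X` (at minimum an intercept, so
`y` is mean-centered). The residualized `y` lives in the orthogonal
complement of the column space of `X`, and the statistic therefore depends
on `K` only through the projected kernel `P K P` with
`P = I - X (X'X)^-1 X'`. The pipeline accordingly computes the null moments
from `tr(PKP)` and `tr((PKP)^2)` (`residual_kernel()`), which is the
moment-matching rule applied to the mixture actually being sampled. The
distinction matters in finite samples: for smooth kernels `1'K1/N` is a
large fraction of `tr(K)`, and using the raw traces shifts the null
noticeably to the right of the truth (only in the conservative direction,
but enough to cost power). `gamma_null_params()` itself is literal — it
uses the traces of whatever matrix it is given — so both conventions are
available.

For a rank-r projection kernel no approximation is needed: all its nonzero
eigenvalues equal 1, the mixture collapses to `N^2 T ~ chi^2_r`, and the
p-value equals the classical `N R^2` score test of the regression of `y`
on the centered transformed coordinates (`sparkx_pvalue()`; the
equivalence is asserted to 1e-10 in the test suite).

The gamma approximation is validated against a Monte-Carlo null of 50,000
centered Gaussian draws at N = 100: at mid-grid lengthscales the upper-tail
CDF discrepancy is below 0.02. At the shortest grid lengthscales (kernels
close to diagonal) the approximation is visibly conservative (discrepancy
up to ~0.07, always in the direction of larger p-values), which depresses
power slightly but never inflates type-I error.

### Indefinite cosine kernels

Our derivations assume a positive-definite kernel; the cosine matrix is
not. `truncate_negative_eigenvalues()` offers the nearest-PSD repair
(zeroing negative eigenvalues), but `pd_adjust` defaults to off: the
unadjusted kernel needs no `O(N^3)` eigendecomposition, and in the null
simulations run by the test suite the unadjusted statistic is conservative,
not inflated (a negative statistic simply yields p = 1 under the gamma
upper tail). GP *sampling* from a cosine covariance, by contrast, always
applies the repair — a sampling covariance must be PSD.

## Aggregation, covariates, FDR

With R kernels per gene, the per-kernel p-values are combined by the
Bonferroni minimum-p rule `min(1, R min p)` (the Sidak variant is available
via `min_p_method`). The rule is conservative under the strong dependence
among kernels — visible in all our null simulations as rejection rates of
1–3% at a nominal 5% — and the combined SMASH p-value includes all four
kernel classes. The seven projection-kernel p-values are separately
combined with the Cauchy rule (mean of `tan((0.5 - p) pi)`, mapped back),
reproducing the SPARK-X aggregate; both result sets are reported side by
side by `run_smash()`.

Covariates are handled by residualization: `y* = (I - P_X) y`. Degenerate
genes (zero residual variance, e.g. constant expression) are kept in the
output with p = 1 so rows always align with the input.

Multiple testing across genes uses Benjamini–Yekutieli by default (valid
under arbitrary dependence; BH available), at level 0.05 (0.01 supported).
P-values are clipped to `[1e-300, 1]` to keep `-log10 p` finite in reports.

## The simulators and what they do (not) emulate

Three generators (`simulate_dataset()`) exercise every statistical claim
without external data:

1. **`nb_pattern`** — negative binomial counts with a mean-level pattern.
   Locations are uniform in the window; `round(0.2 N)` of them form the
   pattern (streak: the band with the largest x-coordinate; hotspot: the
   locations nearest the window center; `reverse_*`: same mask, elevated
   mean on the complementary side). Signal genes have mean
   `fold × base_mean` on the elevated side; `fold = 1` is the null. The
   defaults `base_mean = 2`, `dispersion = 10` (NB size) are this package's
   choices of a realistic moderately overdispersed count regime; they are
   stand-ins, as the corresponding upstream settings are not printed
   anywhere we could copy them from.
2. **`gp_gaussian`** — each gene i.i.d. from `N(0, h K_l + (1 - h) I)`
   with the unit-diagonal Gaussian kernel; the spatial share `h` and noise
   share `1 - h` sum to one, so the marginal variance is 1 by construction
   (checked to Monte-Carlo precision by the acceptance script).
3. **`gp_cosine`** — the same with the cosine kernel, PSD-repaired before
   sampling.

The default window is `[0, 5] × [0, 5]`. The window side is deliberately
several times the smallest simulated period (0.5): a period much smaller
than the tissue is the regime in which periodic covariance is genuinely
*higher-order* — invisible to mean-level projection tests, whose smooth
transformed-coordinate features carry no energy at sub-unit wavelengths —
while remaining detectable by a kernel family whose grid reaches the
sampling resolution. On a unit window a period of 0.5 spans half the
tissue and even a first-order method picks it up, which defeats the point
of the comparison. Sample sizes in the test suite are N = 500–1000 with
150–500 genes and 3–5 replicates; these sizes keep the whole suite under a
few minutes while leaving Monte-Carlo error near or below the assertion
tolerances (a rejection-rate SE of about 0.02).

What the simulators do **not** emulate: platform artifacts (spot size,
segmentation error, dropout), mean-variance trends across genes, and
between-gene dependence. One practical consequence shows up with the
default library-size normalization (`log1p_scaled`): on a small panel in
which a large fraction of genes carries the same strong pattern, per-spot
rescaling transfers a compositional, reversed copy of that pattern onto the
null genes — those detections are real covariation created by
normalization, not a calibration failure. With realistic panel sizes (
thousands of genes, a few percent spatially variable) the effect is
negligible. The statistical calibration tests therefore feed the test raw
per-gene data, and the permutation-calibration checks normalize before
permuting (permutation destroys all spatial pairing, induced or not).

## Numerical choices

* `tr(K^2)` via sum of squared entries; symmetry is enforced after every
  reconstruction (`(A + A')/2`).
* Residualization via QR (`qr.resid`), never explicit `(X'X)^{-1}`.
* Projection kernels use the orthonormal QR basis; in the batched pipeline
  only the N × r basis is formed, never the N × N hat matrix.
* Degenerate inputs: rank-deficient designs and collinear transformed
  coordinates are errors; a degenerate grid span collapses to a single
  deduplicated value; all-zero distance sets are errors.
* Ties in the per-gene best kernel are broken by larger statistic, then
  kernel order; the gene ranking for enrichment scores breaks p-value ties
  by statistic, then input order, so both are deterministic.
* All random generation flows through seeded draws that restore the
  caller's RNG state (`withr::with_seed`).

## Evaluation utilities

`power_table()` averages rejection rates at level alpha over replicate
simulations, separately for signal genes (power) and null genes (type-I
error). `qq_points()` pairs sorted p-values with uniform order-statistic
expectations on the `-log10` scale for calibration plots.
`build_marker_sets()` ranks genes by between-group fold change (pseudocount
1e-9) and keeps the top 50 per label; `enrichment_score()` is the
unweighted GSEA running sum — `+1/|set|` at hits, `-1/(L - |set|)` at
misses — reported as the signed maximum deviation (positive = concentrated
at the top; the sign convention is ours, chosen so that enrichment of true
markers among top-ranked SVGs is positive). `monte_carlo_null()` supplies
the empirical null that validates the gamma approximation.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config("gp_cosine", n = 500, n_genes = 100, param = 0.5,
                  h = 0.4, seed = 7)
sim <- simulate_dataset(cfg)
res <- run_smash(sim$Y, sim$S)
summary(res$p_smash)
rejection_rate(res$p_smash, 0.05)   # near 1: the kernel family sees it
rejection_rate(res$p_sparkx, 0.05)  # near 0: first-order tests do not
```

## Known limitations

* Dense N × N kernels: memory `O(N^2)` and time `O(N^2 K)`; no low-rank or
  sparse approximations are provided.
* The minimum-p aggregate is conservative by design; calibrated-but-
  conservative p-values cost some power relative to an exact combination.
* The gamma null is an asymptotic two-moment approximation; for kernels at
  the sampling-resolution end of the grid it is conservative rather than
  exact.
* Detection is limited to structure expressible by the kernel family; a
  periodic signal between two grid periods can be missed by the cosine
  kernels and is then caught, if at all, by the short-lengthscale Gaussian
  kernels.
* Normalization is the user's responsibility to choose; the compositional
  caveat above applies to any global library-size scaling.
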