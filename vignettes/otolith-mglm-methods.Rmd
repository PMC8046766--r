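---
title: "Model-based stock delineation from otolith shape and chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based stock delineation from otolith shape and chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Otoliths — the calcified ear stones of fish — record both the chemistry of
the water a fish lived in and a species- and population-specific shape.
Both are standard natural markers for *stock delineation*: deciding whether
fish caught at different locations belong to groups that mix regularly (one
management unit) or not (separate units). A typical study yields, per fish,
a dozen trace-element concentrations and several dozen outline-shape
coefficients, measured on only a few dozen fish per site.

Two statistical properties of such data break the distance-based tools
(PERMANOVA on Euclidean distances, nMDS ordination) traditionally applied
to them:

1. **A strong mean–variance relationship.** Concentrations and shape
   coefficients are non-negative with variance rising with the mean
   (Taylor's power law). Distance-based tests assume homogeneous
   multivariate dispersion; when a site simply has lower *means* its points
   also sit closer together, so location and dispersion effects are
   confounded, hypothesis tests lose calibration, and ordinations render
   low-mean groups as spuriously "tight" clusters.
2. **Exact zeros.** Elements below the instrument's detection limit appear
   as zeros, which neither Gaussian nor gamma models accommodate, and which
   `log(y + 1)` transforms merely hide.

`otostock` implements the model-based alternative: multivariate generalised
linear models (MGLMs) whose per-variable error structures encode the
mean–variance relationship directly, with a Tweedie distribution for
chemistry (handling the zeros through its point mass) and a gamma
distribution for shape.

## The model

For fish $i$ and response $j$ (an element:Ca ratio or a shape
coefficient), the model is a GLM with log link and site factor:

$$E(y_{ij}) = \mu_{ij}, \qquad \log \mu_{ij} = \beta_{0j} +
  \beta_{\mathrm{site}(i),j}, \qquad
  \mathrm{Var}(y_{ij}) = \phi_j \,\mu_{ij}^{\nu}.$$

The variance power $\nu$ selects the family. For $1 < \nu < 2$ this is the
Tweedie compound Poisson–gamma distribution: the sum of a
Poisson($\lambda$) number of gamma variables with
$\lambda = \mu^{2-\nu}/(\phi(2-\nu))$, gamma shape
$\alpha = (2-\nu)/(\nu-1)$ and scale $\gamma = \phi(\nu-1)\mu^{\nu-1}$. It
is continuous on $(0,\infty)$ with point mass
$P(Y=0) = e^{-\lambda}$ — exactly the structure of censored chemistry
data, where $P(Y=0)$ is the model's probability that an element falls
below detection. At $\nu = 2$ the distribution is the gamma with shape
$1/\phi$ and scale $\phi\mu$, appropriate for the strictly positive shape
coefficients. The package fixes $\nu = 1.75$ for chemistry and
$\nu = 2$ for shape; $\nu$ is not profiled (see *Design choices*).

**Testing.** Each response gets a site-factor fit and an intercept-only
fit; the per-response likelihood-ratio statistic
$LR_j = 2(\ell_{\mathrm{full},j} - \ell_{\mathrm{null},j})$ is summed
into the multivariate statistic $\sum_j LR_j$. Inference permutes the
site labels (rows are exchangeable under the null), re-running the whole
fitting pipeline — including dispersion estimation — for every
permutation, with
$p = (1 + \#\{\text{permuted} \ge \text{observed}\})/(1 + B)$. The
decomposition $100 \cdot LR_j / \sum_k LR_k$ plays the role a SIMPER
analysis plays in the distance world: it names the variables driving the
multivariate difference. Mixed panels (chemistry + shape) simply
concatenate columns with per-column families; the statistic is additive
across blocks by construction.

**Diagnostics.** Dunn–Smyth (randomised quantile) residuals
$r_{ij} = \Phi^{-1}(F(y_{ij};\hat\mu_{ij},\hat\phi_j,\nu))$ are standard
normal under a correctly specified model even in the presence of the zero
atom (zeros draw $u \sim U(0, F(0)]$; positive observations are
deterministic). Mean–variance plots of per-site sample moments reveal
whether the assumed power law matches the data.

**Ordination.** The model-based ordination fits intercept-only GLMs,
transforms the data to residual normal scores (a Gaussian-copula view of
the fitted margins), and extracts two factors from the residual
correlation matrix by eigendecomposition. Because the margins absorb the
mean–variance structure, between-site separation appears as score shifts
rather than as artificial spread differences.

## What the comparator track is for

`euclidean_distances()`, `dispersion_test()`, `permanova()` and `nmds()`
reproduce the traditional workflow — not because it is recommended, but
because demonstrating its assumption failures on zero-inflated,
mean–variance-structured data is half the point. `run_pipeline()` runs the
dispersion homogeneity test first and flags the PERMANOVA/nMDS results
`assumption_violated` when it rejects at $P < 0.05$. The dispersion test
embeds the distance matrix in principal coordinates and applies a one-way
ANOVA to the distances from each sample to its group *centroid* (the
deterministic variant; spatial medians are the common default elsewhere),
combining real and imaginary axes as
$\sqrt{\max(0, d^2_{\mathrm{real}} - d^2_{\mathrm{imag}})}$.

## The shape pipeline

Outlines (closed polygons) are smoothed by 100 passes of three-point
neighbour averaging, converted to a 512-point centroid-radius function
$r(\theta)$ with the angular origin anchored at the outline point farthest
from the centroid (a deterministic rotation registration), and transformed
with a periodic orthonormal discrete wavelet transform (Daubechies
least-asymmetric, order 4; configurable). The six coarsest detail levels
— $1+2+4+8+16+32 = 63$ coefficients — describe shape at scales from the
whole outline down to $1/32$ of its circumference and reproduce over 99%
of the radius variance of smooth otolith-like outlines; the level-9
scaling coefficient is pure size and is excluded from testing.
Coefficients are standardised for fish length by removing the pooled
within-site regression slope on total length (so genuine site differences
are not removed along with allometry), and mapped to strict positivity for
the gamma family by a per-column affine shift to the observed support plus
a small offset (an absolute-magnitude variant is available; neither is
canonical, and the choice is exposed as an argument). Per-site mean shapes
are reconstructed by inverse-transforming mean coefficient vectors.

## Chemistry preprocessing

Concentrations strictly below the per-element detection limit become exact
zeros (values at the limit are kept; no limit/2 substitution — the zeros
*are* information the Tweedie point mass models). Concentrations convert
to element:Ca molar ratios,
$(\mathrm{ppm}_e / M_e) / (\mathrm{ppm}_{Ca} / M_{Ca}) \times 1000$
mmol:mol, using packaged IUPAC atomic masses, normalising for otolith
mass.

## The synthetic generator

Every stage is testable without field data through `synthetic_config()`
and its generators, which emulate the three-river study design the package
grew from: 3 sites × 18 fish; 12 element:Ca ratios from Tweedie
distributions with variance power 1.75, one "Agra-like" site highest for
10 of 12 elements, a "Narora-like" site highest for Zn and Mg, a
"Lucknow-like" site lowest for all; Zn and Cd means low enough that exact
zeros occur at realistic rates (a few per 18 fish); 63 strictly positive
gamma shape coefficients (shape parameter 20) with deliberately weak site
effects, so the chemistry block dominates the combined statistic as in the
motivating study; site-specific fish lengths with the largest fish at the
Agra-like site; and harmonic star-shaped outlines
$r(\theta) = a(1 + c_2\cos 2\theta + c_3\cos 3\theta)$ with weakly
site-dependent $c_2$, fish-level amplitude noise and vertex jitter. The
mmol:mol magnitudes (Na and Sr largest, trace metals small) are realistic
for freshwater otoliths but are configuration, not truth.

What the generator does **not** emulate: instrument drift and blank
correction, between-element correlation beyond what the site means induce,
non-star-shaped or crenulated outlines, and measurement error in fish
length. Passing tests therefore certify the statistical machinery, not
instrument-level data quality.

## Numerical choices

* **Series evaluation.** The Tweedie log-density sums the compound
  Poisson–gamma series on the log scale around the dominating Poisson
  index, truncating when a term's relative contribution drops below
  1e-12. The CDF uses the same representation —
  $e^{-\lambda} + \sum_N \mathrm{Pois}(N;\lambda)\,
  \mathrm{Gamma\,CDF}(y; N\alpha, \gamma)$ — truncated when the remaining
  Poisson tail is below 1e-14; this is exact, shares the truncation
  machinery, and needs no caching or quadrature. Quadrature survives in
  the test suite as the independent normalisation oracle.
* **Dispersion.** $\phi_j$ is estimated by maximising the exact
  likelihood (1-D search on $\log\phi$), not by a moment/deviance
  estimator, because the LR statistics depend on likelihood values. The
  bounded search starts from a wide window around the moment estimator
  $\widehat{\phi}_{\mathrm{mom}} = \mathrm{mean}((y-\hat\mu)^2 /
  \hat\mu^{\nu})$ and expands toward the hard bounds
  ($\phi \in [10^{-8}, 10^4]$) whenever the optimum lands on an interior
  edge, so the result is the global bounded ML solution while the series
  never needs pathological term counts. Degenerate (constant) data are
  clipped at the lower bound.
* **Mean estimation.** IRLS with log link, convergence at 1e-10 on
  coefficients; for the factor-only designs in scope this converges to
  the group sample means from the exact start in one step. Zero-mean
  groups are guarded by machine epsilon.
* **Permutation scheme.** Row-label permutation with $B = 999$ by
  default, p-value floored at $1/(B+1)$. Permutation is exact under
  exchangeable rows and deterministic given a seed; resampling engines
  based on bootstrap weighting would leave the statistic unchanged and
  move p-values only slightly.
* **Gamma boundary.** `tweedie_logpdf(0, ..., power = 2)` returns
  `-Inf` rather than raising, keeping the numerics total; fitting code
  validates strict positivity of gamma-family columns up front and names
  the offending column.
* **nMDS.** Classical-scaling start, Kruskal stress-1 via monotone
  regression, tolerance 1e-6, at most 200 iterations; stress reported as
  a fraction, conventionally printed to 2 decimals.
* **Degenerate distances.** All-identical point sets yield pseudo-F 0
  (p = 1) in PERMANOVA and a zero-dispersion result rather than an
  exception.

## Problem sizes in the test suite

The shipped tests run the full study design (54 fish, 12 + 63 responses)
for single analyses; calibration claims use 100–200 simulated replicates
with $B = 199$ permutations and Monte-Carlo draws of $10^5$ for
distributional checks — sizes at which binomial/Monte-Carlo error is well
inside the asserted bands. One property deserves a note: with 18 fish per
site, the ratio of two within-site score variances fluctuates like an
F(17,17) variable, so the "equal spread per site" property of the
model-based ordination is asserted on the median across seeds (and
comparatively against nMDS), not seed-by-seed.

## Known limitations

* $\nu$ is fixed, not estimated; misspecifying it distorts dispersion
  estimates, though the permutation test remains level under the null.
* The sum-of-LR statistic grows with the number of responses (each
  contributes roughly a $\chi^2_2$ under the null), so raw statistics are
  comparable only between analyses with the same column count — another
  reason inference is by permutation.
* The copula ordination extracts exactly two factors by
  eigendecomposition; it is a visualisation, not a full graphical-model
  estimate, and its agreement with MCMC latent-variable ordinations is
  qualitative (separation patterns), not numeric.
* The shape pipeline requires star-shaped outlines; strongly lobed or
  crenulated otoliths violate the polar parameterisation and are rejected
  with an explicit error.
* Wavelet coefficients destined for the gamma family pass through a
  positivity mapping whose choice (shift vs magnitude) is not canonical;
  conclusions should be checked under both when shape inference is
  borderline.

## A minimal session

```{r, eval = FALSE}
library(otostock)

cfg <- synthetic_config()
res <- run_pipeline(cfg, B = 999, seed = 1, out_dir = "results")

res$mglm$chemistry          # sum-of-LR, P, per-element decomposition
res$distance$chemistry      # dispersion F, PERMANOVA F, nMDS stress
res$ordination$combined     # two-factor model-based ordination
```
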