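---
title: "Random projection segmentation of MSI data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random projection segmentation of MSI data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msirp)
```

This vignette is the package's account of its methods: the model and its
assumptions, the parameters that matter, the numerical choices, what the
synthetic phantom establishes and what it cannot, and the places where the
design was genuinely open and a choice had to be made.

## The model

A mass spectrometry image is a matrix $X_{m \times n}$: $m$ m/z channels,
$n$ pixels, typically $m \gg n$. Segmentation asks for a partition of the
pixels by spectral similarity under the Euclidean metric. Working directly in
$m$ dimensions is slow and, worse, distance contrast degrades as
dimensionality grows. `msirp` reduces dimension with a random projection: a
matrix $Q_{k \times m}$ of i.i.d. $\mathcal{N}(0,1)$ entries, applied as
$A = QX$. Three properties drive the whole design:

1. **Data independence.** $Q$ requires nothing from the data, so scores can
   be computed pixel by pixel as spectra arrive; the package's streaming
   contract (one chunk of spectra in memory at a time) holds for every
   full-data pass, including the PCA baseline.
2. **Distance preservation.** For any pair of spectra, the scaled projected
   distance $\|Qx_1 - Qx_2\|/\sqrt{k}$ concentrates around
   $\|x_1 - x_2\|$ as $k$ grows (Johnson–Lindenstrauss). The stored scores
   are the *raw* products $QX$ — no $1/\sqrt{k}$ factor, no centering, no
   normalization of the input spectra — so the $1/\sqrt{k}$ factor is applied
   externally where distance preservation is measured.
3. **Seeded reproducibility.** Results depend on the draw of $Q$, so every
   basis records its seed and generator. Rows are generated on independent
   sub-streams: row $r$ uses a seed derived from `(seed, r)` under a fixed
   Mersenne-Twister/inversion configuration. Consequently a basis is
   bit-reproducible, and a larger basis is a bit-exact extension of a smaller
   one with the same seed — `extend_basis()` is associative and
   prefix-stable, which is what makes the incremental selection workflow
   below cheap.

## Choosing the number of projections

As rows accumulate, the largest singular value $s_1$ of the score matrix
grows; normalized per projection ($s_1/k'$, the default; $s_1^2/k'$ is
available via `norm = "s1sq_over_k"`) it decays toward a plateau, because
each additional random direction captures less new variance. The selection
procedure is:

1. Measure the curve over row subsets. The default subset policy is **nested
   prefixes** (first $k'$ rows in basis order), making the curve a
   deterministic function of one basis; averaged random subsets are available
   (`policy = "random"`). Prefixes were chosen as the default because they
   are consistent under basis extension and need no averaging.
2. Fit $y(x) = a e^{-bx} + c$ by least squares. The asymptote $c$ is
   essential: the measured curve plateaus, and a two-parameter exponential
   would be forced into a biased $b$. Fitting is deterministic — variable
   projection over a log-spaced grid of decay rates (the linear parameters
   $a, c$ are profiled out exactly), golden-section refinement of $b$, then
   full Levenberg–Marquardt with an analytic Jacobian. Non-convergence is
   reported as a flag, never as silent numbers; a zero-variance curve is
   returned as a degenerate flat fit ($a = 0$).
3. Find the elbow analytically. With $u(x) = ab\,e^{-bx} = |y'(x)|$ the
   curvature is $\kappa = b\,u/(1+u^2)^{3/2}$, maximized at $u = 1/\sqrt2$,
   i.e. $x^\* = \ln(\sqrt2\,ab)/b$ when $ab \ge 1/\sqrt2$ and at the boundary
   $x^\* = 0$ otherwise.
4. Select the smallest $x > x^\*$ with $\kappa(x) = \tfrac23 \kappa(x^\*)$
   (the fraction is a parameter; κ is strictly decreasing on that branch so
   bracketed root-finding on $[x^\*, x^\* + 20/b]$, expanded geometrically if
   needed, is safe) and **round up**. Rounding up is conservative: extra
   projections cost time, never correctness.
5. If the selected count exceeds the measured range (`elbow_reached()` is
   `FALSE`), extend the basis and repeat; the pipeline's `"auto"` mode does
   this loop with a hard cap (`max_projections`, default 512).

Two readings of the two-thirds rule are possible — a threshold on the
curvature *value* (implemented, supported by the procedure's description) or
on some curvature-drop distance; the value reading is used and tested.

**Limitation worth knowing.** On projected real or phantom data the measured
$s_1/k'$ decay is closer to a power law ($s_1$ of a Gaussian sketch grows
like $\sqrt{k'}$) than to a true exponential. The exponential fit still
tracks the curve well enough to flag the plateau, but the selected count can
vary substantially between bases (on the bundled phantom, roughly 40–170 at
$k = 200$). The package therefore treats $k$ as an experimental variable with
an automated *estimate*, not a guarantee; the ±10% stability property is
asserted where it actually holds — on curves that are exponential by
construction.

## Segmentation

Lloyd k-means on the $n$ score columns in $k$ dimensions, Euclidean metric.
Policies, all explicit and seeded:

* **Initialization**: $D^2$-weighted sampling of data columns (k-means++
  seeding), best of `n_restarts = 10` runs by within-cluster squared distance
  (inertia). Plain uniform sampling of columns was tried first and discarded:
  with a small, well-separated class (the phantom's 197-pixel core), uniform
  initialization misses it often enough that all ten restarts can converge to
  a split of the largest region instead (observed inertia 1.008e11 vs
  9.7e10), and the planted partition is lost.
* **Empty clusters**: re-seeded to the point farthest from its current
  centroid, then iteration continues.
* **Convergence**: labels unchanged or relative inertia change < 1e-6, at
  most 300 iterations. Inertia is recorded per iteration and is
  non-increasing (asserted in tests on reseed-free runs).
* **Ties**: nearest-centroid ties break to the lowest cluster index;
  assignment is therefore invariant to permuting the projection rows.

The number of clusters is user-supplied; the package deliberately ships no
model-selection rule for it. Cluster *profiles* (mean spectra) are always
recomputed from the raw spectra in a single streaming pass — scores are
sign-mixed linear combinations and cannot be read as chemistry.

## Evaluating reproducibility

"Correlation between segmentation maps" is undefined for categorical labels,
so the package uses a label-permutation-invariant reading: the Pearson
correlation between co-assignment indicators over pixel pairs (all pairs for
$n \le 2000$, otherwise $10^6$ seeded pairs, keeping cost independent of
$n$), with the adjusted Rand index reported alongside. If either indicator is
constant on the sampled pairs the correlation is undefined; the implementation
returns 1 if the co-assignment structures are identical and 0 otherwise.
`stability_experiment()` repeats basis → projection → segmentation with
independent seeds per projection count and tabulates all pairwise agreements;
on the bundled phantom the mean agreement is about 0.24 at 5 projections and
1.0 at 150 — the low-$k$ instability / high-$k$ stability regime the method
is designed to expose.

The PCA baseline (`pca_scores()`) uses mean-centered, unscaled data (standard
PCA convention; scaling is deliberately not offered since channel units are
homogeneous). It honors the same streaming contract: pass one accumulates the
mean spectrum, pass two the $m \times m$ scatter in chunks, pass three the
component scores. The top eigenvectors come from a seeded randomized subspace
iteration (Gaussian sketch, 10 oversamples, 3 power iterations) — exact
whenever `n_components + 10 >= m`, and accurate for the leading, separated
components that drive segmentation otherwise; it is deliberately *not* the
same code path as the full-SVD oracle used to test it.

Maximum-window peak picking is a diagnostic for spectral complexity, not part
of the segmentation path: channel $i$ is an apex iff it is the *strict*
maximum over an odd window centered on it and above a threshold. Exact
intensity ties (possible only on synthetic, noise-free data) are therefore
not peaks. The reported centroid is the intensity-weighted mean m/z over the
window, giving sub-channel accuracy with an exactly testable definition.

## The phantom: what a green test establishes

`default_liver_like_spec()` states the package's test world: a 64 × 64 grid,
4000 channels over m/z 600–950 (a typical lipid-mode MALDI acquisition
range), four contiguous regions — fibrotic-like ribbon (640 px), hepatocyte
blob (704 px) with a nested regenerating core (197 px) sharing 30 of its 40
peaks, and a matrix-only remainder — over 15 shared matrix peaks. Peak shapes
are Gaussians with SDs of 0.18–0.35 Da (a few channels wide; adequate for a
TOF-like resolving power without modeling detector physics). Noise is
additive Gaussian (SD 10 counts) plus an 8 % per-pixel multiplicative gain
jitter, clamped at zero. The additive level was calibrated once, before the
acceptance tests were frozen, so that the phantom sits in the regime the
method targets: per-spectrum noise comparable to the smallest between-class
profile difference, where 150 projections recover the planted partition
essentially perfectly while 5 projections give unstable, basis-dependent
maps.

What the phantom does **not** emulate: isotope envelopes, matrix-cluster
chemistry, mass-calibration drift, correlated (structured) noise,
non-rectangular acquisitions, and TIC variation beyond a scalar gain. A green
phantom test therefore establishes algorithmic correctness (streaming
equivalence, distance preservation, recovery under the stated noise model),
not instrument-level robustness.

## Numerical and format choices

* Intensities are processed as 64-bit floats end to end; negative input
  intensities are clamped to zero with a warning (the dataset invariant wins
  over silent propagation). Spectra are **not** TIC-normalized or centered
  before projection — projections apply to raw data by design.
* Pixel coordinates are 1-based; iteration order is ascending (y, x)
  everywhere, which pins down every seeded downstream result.
* Processed-mode imzML has no shared axis; spectra are resampled by summing
  peak intensities into fixed-width bins spanning the global m/z range.
  `bin_width` has **no default** — any default would silently set the
  effective resolution — so a processed file without a configured width is a
  configuration error.
* imzML writing is continuous-mode, uncompressed 64-bit, with the file
  identifier derived from a content hash rather than a random UUID so that
  fixed-seed pipeline runs are byte-identical.
* The exponential fit's determinism, the closed-form elbow, the root-finding
  bracket, and the k-means policies above are all covered by oracle tests
  (power iteration for $s_1$, dense-grid maximization and root-finding for
  the curvature analytics, brute-force pair counting for the Rand index,
  batch group-by for streaming accumulations).

## Known limitations

* Scores are not invertible to m/z space; cluster interpretation must go
  through the recomputed raw-spectrum profiles. Orthonormalized random bases,
  sparse/±1 projections, and formal bounds on $k$ are out of scope.
* The selected projection count inherits the variability of the exponential
  fit on non-exponential curves (see above); treat it as a starting estimate
  and prefer the stability experiment when reproducibility matters.
* Only uncompressed 32/64-bit float imzML arrays are supported; vendor
  formats and mzML are not read.
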