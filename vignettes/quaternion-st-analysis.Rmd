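---
title: "Quaternion models and hypercomplex Fourier analysis of spatial transcriptomics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quaternion models and hypercomplex Fourier analysis of spatial transcriptomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quatst)
```

## The model

Spatial transcriptomics (ST) assays measure UMI counts for thousands of
genes at thousands of tissue locations. `quatst` compresses each location's
profile into a single quaternion

$$q = a + b\,i + c\,j + d\,k,$$

where the real part $a \ge 0$ carries sequencing depth and the vector part
$(b, c, d)$, normalized to unit length, carries a three-dimensional
relative expression direction. Two ideas motivate this compression:

* **Depth is uncertainty.** After library-size normalization, locations
  with few reads have noisy relative profiles. Keeping depth as the real
  part (rather than dividing it away) preserves that information: in the
  false-colour rendering it becomes opacity, so unreliable locations
  literally fade out.
* **State transitions are rotations.** Unit vectors in $\mathbb{R}^3$
  differ by rotations, and rotations have a compact, composable quaternion
  representation $v' = r v r^{-1}$ with
  $r = \cos(\theta/2) + \sin(\theta/2)\,\hat u$. The rotation axis
  $\hat u$ is itself a transcriptomic state — the state *invariant* under
  the transition — which gives rotation-based analyses a direct biological
  reading.

Because a whole tissue then becomes a quaternion-valued raster, the
machinery of hypercomplex image analysis applies: a single 2D
quaternion-domain discrete Fourier transform (QFT) of the joint
four-channel signal, spectral filtering, and convolution, none of which
reduce to independent per-gene transforms.

### Mapping models

Three mappings produce the per-location quaternions:

* **SVD model** (`svd_model`). With $X$ the unnormalized $n \times p$
  count matrix and $X = U D V^\top$, project onto the first four singular
  vectors, $P = U_4 D_4$. Then $a_i = |p_{i1}|$ and
  $(b, c, d)_i = (p_{i2}, p_{i3}, p_{i4}) / l_i$ with
  $l_i = \|(p_{i2}, p_{i3}, p_{i4})\|$. For count data the first singular
  vector is close to the profile-weighted depth direction, so $|p_{i1}|$
  tracks library size; the remaining components capture the dominant
  relative-expression contrasts.
* **Gene model** (`gene_model`). The vector part is the expression of
  three marker genes — optionally the rank-$r$ SVD reconstruction
  $\hat X = U_r D_r V_r^\top$ to denoise — normalized to unit length; the
  real part is the location's library size (or, by flag, the summed
  counts of the three genes). Reconstruction operates on raw counts by
  default, consistent with the SVD model's use of unnormalized data; a
  library-size-normalization flag is provided.
* **Gene-set model** (`geneset_model`). Accepts any caller-provided
  $n \times 3$ score matrix (set scores, cell-type proportions, ...) plus
  depths, and only assembles quaternions; scoring itself is deliberately
  out of scope.

### The quaternion Fourier transform

`qfft2` uses the Cayley–Dickson decomposition $q = \alpha + \beta j$ with
complex $\alpha = a + bi$, $\beta = c + di$. Since
$e^{-i\theta}(\alpha + \beta j) = (e^{-i\theta}\alpha) +
(e^{-i\theta}\beta)j$, two standard complex FFTs of the $\alpha$ and
$\beta$ planes assemble to $F = F_\alpha + F_\beta j$, which is exactly the
**left** one-sided QFT with transform axis $i$:

$$F(u, v) = \sum_{m,n} e^{-i 2\pi (um/R + vn/C)}\, Q(m, n),$$

the exponential multiplying from the left. Other QFT conventions
(two-sided, axis $\mu \ne i$) exist in the hypercomplex signal-processing
literature; only this one is offered because it is the one the
Cayley–Dickson recipe computes. The forward transform is unnormalized and
the inverse carries $1/(RC)$, matching the common FFT convention. The test
suite pins the implementation against an $O((RC)^2)$ double-sum oracle
built directly from the definition.

### Convolution and biconvolution

Real-valued kernels (the classic sharpening and edge kernels are built in)
commute with quaternion values, so `convolve_real` runs one complex FFT
convolution per coefficient plane — exact circular convolution. By default
only the vector planes are convolved and the depth plane passes through
(`vector_only = TRUE`), since depth is metadata, not signal.

Quaternion-valued masks do not commute, so `biconvolve` computes the
sandwich $M_L * X * M_R$ with the product order preserved, through the
Cayley–Dickson identities

$$(C_1 + C_2 j)(A + B j) = (C_1 A - C_2 \bar B) + (C_1 B + C_2 \bar A) j$$

and its right-sided counterpart, each term one complex FFT convolution.
This FFT path equals the spatial double convolution exactly (the suite
checks it against a triple-loop oracle at $10^{-9}$ relative error).

`rotation_kernels(r)` builds the $3 \times 3$ pair with rows
$(r, 0, r^{-1})$ on the left and $(r^{-1}, 0, r)$ on the right. A subtlety
worth stating precisely: biconvolution with this pair does **not** produce
a smaller raw magnitude on boundaries aligned with the rotation axis.
What holds — and what the tests assert — is a plane separation: the output
component *along* the axis responds only to changes along the axis, and
the output component *orthogonal* to the axis responds only to orthogonal
changes. "Edge detection in the space orthogonal to the axis" therefore
means reading the off-axis output planes, where changes along the axis are
invisible. With $r$ a half-turn about $i$, edges in the $j$/$k$ channels
of the rendering come only from $j$/$k$ transitions.

### Spectral filtering

"Remove the top $n$ frequency components" is interpreted radially: cells
of the spectrum are ranked by the centred radial frequency
$\rho(u, v) = \sqrt{(u'/R)^2 + (v'/C)^2}$, and `spectral_filter` zeroes
the $n$ distinct highest (lowpass) or lowest (highpass; DC included)
$\rho$ *bands*. Banding keeps conjugate-symmetric cell pairs together so
filtered real inputs stay real; counting individual FFT cells instead
would split such pairs and is not offered. $\rho$ values are rounded to
10 decimals before banding to absorb floating-point ties.

## Grid construction

`build_grid` bins locations into an $R \times C$ raster with uniform
half-open bins over the coordinate extent (last bin closed); $y$ maps to
rows with descending $y$ — the image convention — and $x$ to columns.
Choices made where several behaviours would be defensible:

* **Collisions** (two locations, one cell) are averaged coefficient-wise
  and the vector part renormalized to unit length, keeping the mapping
  models' unit-vector invariant. Last-write-wins would make the grid
  depend on row order.
* **Hole fill-in**: cells inside the convex hull of observed cells that
  received no location are replaced by the coefficient-wise mean of their
  non-empty 8-neighbours (vector part renormalized), iterating until no
  reachable hole remains, capped at 10 passes. Each pass uses the state
  at the start of the pass, so deep holes fill layer by layer. Cells
  outside the hull stay exactly $(0,0,0,0)$ and are flagged `empty`,
  preserving the tissue boundary; `observed` cells are never modified.
* **Degenerate extents** (all $x$ or all $y$ equal) are an error rather
  than a single-row grid.

Grids serialize to a plain-text container (header plus one CSV row per
cell) with coefficients printed at 17 significant digits, which
round-trips IEEE doubles bit-faithfully.

## Rotation analyses

`difference_length` reports the per-cell Euclidean length of the vector
part of $Q - Q_\text{rot}$. Geometry gives the closed form
$2\,|\sin(\theta/2)|\,\|v_\perp\|$, which the tests use as an analytic
oracle for every rotation map. Note the range: a *unit* vector orthogonal
to the axis under a half-turn moves by chord length 2 (the diameter), not
1; low values mark profiles aligned (or anti-aligned) with the axis.

`estimate_perturbation_rotation` summarizes each location set by the
chordal mean of its unit vector parts (coefficient-wise mean,
renormalized) — the standard estimator for tight direction clusters — and
returns the minimal rotation between the two means. Two estimator
subtleties are deliberate:

* The minimal rotation between two directions is only identified up to
  the component acting on the mean; the recovery tests therefore plant
  perturbations acting on state clusters spread orthogonally to the
  invariant axis (which is exactly the configuration the interpretation
  "the axis is the unaffected state" describes), and verify recovery
  within 2 degrees under 1 degree of angular noise.
* Pairwise-rotation **dispersion** is $1 - \|\bar q\|$ over sign-aligned
  unit rotation quaternions (the double cover means $q$ and $-q$ encode
  one rotation; alignment is toward the first sampled pair). It is 0 when
  all pairwise rotations agree and grows toward 1; pairs are subsampled
  without replacement, seeded, when the cross product of sets is large.
  Opposing directions whose mean length falls below $10^{-8}$ are an
  error, not a silent near-zero axis.

## Visualization

`to_rgba` maps vector coefficients through the sigmoid
$\sigma(x) = 1/(1 + e^{-2x})$ — chosen so the unit-vector bound
$[-1, 1]$ fills the central, steep part of the curve — and depth through a
quantile-capped log rescale: cap at the `alpha_quantile` quantile (0.9 by
default) computed over non-empty cells, then $\log(x - \min(x) + 1)$,
then linear rescale to $[0, 1]$. Capping is winsorization, not discarding:
discarding would punch holes in the tissue. A location with zero reads is
fully transparent; locations at or above the cap are fully opaque. Empty
cells render neutral grey at alpha 0 (the RGB value there is cosmetic and
invisible). If all depths are equal the rescale is degenerate and opacity
falls back to 1 with a warning.

## Synthetic data

`simulate_fig1` builds the package's worked example: 30 locations by
5 genes in three populations with relative-abundance profiles
$\{0.5, 0.2, 0.1, 0.1, 0.1\}$, $\{0.1, 0.1, 0.1, 0.2, 0.5\}$ and
$\{0.1, 0.3, 0.3, 0.2, 0.1\}$, and library sizes scaling linearly 1-to-10
within each population. The within-population scale is realized as ten
equally spaced multiples of a base depth of 100, which keeps every count
integral and makes rows exact scalar multiples — hence exactly three
collinear direction clusters and a within-population depth ratio of
exactly 10 under the SVD model. The generator is noise-free by default
because exact collinearity is the property being demonstrated.

`simulate_domains` lays expression domains (half-planes, quadrants, or a
disk) on a raster, with library sizes drawn uniformly from a default range
of 100–1000 (the same 1-to-10 span) and multinomial count noise by
default; `noise = "none"` gives deterministic rounded counts for
fixture-style tests. What this generator emulates is contiguous domains
with distinct relative profiles and depth variation; what it does *not*
emulate is the overdispersion, zero inflation, spatial gradients within
domains, and segmentation artefacts of real ST data. Passing tests
therefore demonstrate correctness of the algebra and transforms on
idealized tissue, not robustness to real-data noise.

Note that three-profile count data has rank 3: `svd_model` emits a note
when the matrix has rank below 4 (the fourth projection coordinate is then
identically zero and directions are confined to a plane), errors only
below rank 2, and otherwise proceeds — low-rank mixtures are legitimate
inputs, and the worked example itself is one.

## Numerical conventions

* **SVD sign fix**: for each singular pair the element of $V$ with the
  largest absolute loading is made positive (ties: lowest index).
  Without this, signs — and therefore colours and serialized grids — would
  depend on the LAPACK build.
* **Double cover**: rotation constructors canonicalize the real part to
  be non-negative, so serialized rotations are reproducible.
* **Antiparallel `rotation_between`**: the axis is the normalized cross
  product of $u_1$ with the standard basis vector having the smallest
  absolute component in $u_1$ (ties toward the lowest index) —
  deterministic and orthogonal to $u_1$.
* **Tolerances**: unit-norm admission is $10^{-8}$ and internal
  assertions use $10^{-12}$; both are module-level configuration
  (`quatst_tolerances()`).
* **Zero-direction locations** ($l_i = 0$): the vector part is set to
  $(0, 0, 0)$ and the real part kept; all-zero locations map to the zero
  quaternion with a warning.
* **Boundary handling**: all convolutions are circular (FFT-native);
  padding is not offered in this version, so responses at opposite edges
  of the raster are coupled by wrap-around.

## Problem sizes

The test-suite and worked-example computations are desk-scale by design:
quaternion algebra oracles run on hundreds of random samples, QFT
equivalence on matrices up to $6 \times 7$ (the brute-force oracle is
quadratic in the cell count), convolution oracles on $5 \times 5$ to
$8 \times 8$ rasters, and rotation-recovery simulations on 50 directions.
The library functions themselves are FFT- and BLAS-bound and scale to the
$10^5$-location rasters produced by high-definition ST assays; the
randomized SVD path (`svd_model(randomized = TRUE)`, a seeded Halko-style
range finder computing only the top four factors) exists for exactly that
regime.

## Limitations

* Only a rank-3 slice of the expression space is represented; biological
  signal outside the first four singular vectors (or the three chosen
  genes/sets) is invisible to the model.
* The QFT convention is fixed (left-sided, axis $i$); analyses that
  require two-sided or axis-general transforms are out of scope.
* Raw biconvolution magnitude is not axis-selective (see above); users
  should interpret the output plane-wise.
* No correction is attempted for rotation/alignment mismatch between
  stated coordinates and the physical array; coordinates are binned as
  given.
* Octonion extensions, 1D pseudotime transforms, and trajectory
  likelihoods are out of scope.

## A worked end-to-end example

```{r example, eval = FALSE}
x <- simulate_fig1()
lq <- svd_model(x)

# three collinear clusters
v <- vec_part(lq$q)
round(v[c(1, 11, 21), ], 3)

# depth ratio within population 1
a <- scalar_part(lq$q)
max(a[1:10]) / min(a[1:10])  # 10

# a spatial dataset: two domains, edge detection at the boundary
s <- simulate_domains(16, 16, noise = "none", seed = 1)
g <- build_grid(gene_model(s, c("gene1", "gene4", "gene5"))$q,
                s$coords, rows = 16, cols = 16)
edges <- convolve_real(g, kernel_edge())
img <- to_rgba(edges)
```
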