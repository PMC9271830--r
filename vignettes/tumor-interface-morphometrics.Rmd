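---
title: "Morphological and fractal analysis of tumor interfaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological and fractal analysis of tumor interfaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tumorfract` characterizes the interface between a brain tumor and the
surrounding tissue with a family of scaling, roughness and shape
descriptors. The guiding physical idea is that the growth process leaves a
geometric fingerprint: a proliferative–invasive (ballistic) growth process
produces a kinetically roughened surface whose local roughness exponent
$\alpha_{loc}$ and fractal dimension $d_F$ satisfy the Family–Vicsek
relation $\alpha_{loc} + d_F = d_E$ (with $d_E = 3$ for a closed surface in
3D), while purely proliferative growth produces smoother, more regular
surfaces that break this identity. This vignette explains each stage of
the pipeline, the tunable parameters and their defaults, the synthetic
data the package validates itself against, and the numerical choices and
limitations a careful user should know about.

## Segmentation by dynamic quantum clustering

Grey levels (digital levels) of a contrast-enhanced volume are clustered
on the 1D intensity axis — spatial coordinates are not clustered. A Parzen
estimator $\varphi$ with Gaussian kernel width $\sigma$ (default: intensity
range / 20) smooths the histogram. Treating $\varphi$ as the ground state
of a Schrödinger operator with zero energy yields the potential
$$V(x) = \frac{\sigma^2}{2}\,\frac{\nabla^2 \varphi}{\varphi},$$
whose local minima act as cluster attractors. Each distinct level then
follows the damped second-order dynamics
$\sigma^2 \ddot x = -V'(x) - \gamma \dot x$, integrated from rest with a
semi-implicit Euler scheme. The scheme is run twice: the first pass
(Dynamic A) clusters the raw histogram; a Parzen re-estimate of the
clustered histogram produces a *trap potential* with sharply separated
minima, under which the original levels are evolved a second time
(Dynamic B). The number of trap minima is the number of classes — no class
count is supplied by the user. On well-separated Gaussian mixtures the
resulting centroids coincide with K-means centroids to within one digital
level, which the test suite checks against `stats::kmeans` as an
independent oracle.

Defaults: $\gamma = 1$, $dt = 0.1/\gamma$ (so $\gamma\,dt = 0.1$, far from
the $\gamma\,dt < 2$ stability bound), $\sigma^2 = \sigma^2_{kernel}$,
convergence when the largest per-step displacement falls below $10^{-4}$
levels. The "mass" $\sigma^2$ is the scientifically meaningful dial:
raising it merges potential minima and coarsens the segmentation
monotonically. $\varphi$ is floored at $10^{-12}\max\varphi$ before the
division; Dynamic A terminal positions are binned at half-level resolution
before re-estimation.

## Interface extraction and parameterization

The tumor interface is the set of tumor voxels with at least one
six-connected non-tumor neighbor. The tumor *center* is the centroid of
the full tumor mask, not of the interface points, so that unevenly sampled
surfaces do not bias the radii. All radii are Euclidean distances to this
center in world coordinates (`world = 0-based index × spacing`; only the
voxel spacing of a NIfTI header is honored).

**Sub-voxel refinement.** Binary voxelization quantizes surface positions
to ~0.3 voxel, which every fluctuation statistic downstream would read as
a noise floor — a voxelized perfect sphere would show an interface width
of ~0.4 voxel that is pure discretization. Each interface point is
therefore moved to the 0.5 level set of a Gaussian-smoothed (σ = 1.2
voxel) copy of the mask along the local normal, clamped to at most one
voxel of displacement. On a voxelized sphere of radius 30 this reduces the
radial scatter from ~0.5 to ~0.06 voxel. The price is a mild suppression
of genuine roughness below ~2 voxels; see *Limitations*.

**Cylindrical grid.** For the 2D analyses the interface is parameterized
as $r(n_\phi, n_Z)$ about the principal axis of the point cloud closest to
the image z-axis (mirroring slice-wise acquisition; ties resolved to image
z). Each (φ, z) bin stores the *maximum* radius among its points — the
outer envelope, which resolves multi-valued radii on non-convex surfaces;
the fraction of multi-valued bins is reported as a quality metric. Bin
counts adapt to the interface size (targeting ~3 points per bin, 2:1
aspect, capped at 96 × 48) so small lesions do not produce mostly-empty
grids. Empty bins are filled by periodic linear interpolation along φ
(fully empty rows along z) and flagged in `fill_mask`.

**Ordered series.** Slice-wise series take the interface points of one
axial slice, ordered by polar angle about the slice centroid, one radius
per angular bin (outer envelope, default 180 bins). The default slice is
the one holding the most interface points, ties to the lower index. On
voxelized closed surfaces this selector can land on a polar tangent slice
(a cap contains many interface voxels); analyses that need an equatorial
cut can pass `slice_index` explicitly.

## Scaling analysis

**Box counting.** $N(\epsilon)$ is the number of occupied boxes on a
geometric ladder of box sizes, averaged over 4 shifted grid origins;
$d_F$ is minus the slope on the best contiguous window (max $r^2$, at
least 5 scales). The ladder's lower end matters: counts saturate once
boxes shrink to the point-sampling scale, so the default ladder stops
descending where boxes would hold fewer than ~3 points on average. The
upper end is a quarter of the bounding box.

**Lacunarity.** Gliding-box occupancy statistics
$\lambda(\epsilon) = \mathrm{var}/\mathrm{mean}^2$ of the per-box point
count. The printed formula in parts of the literature
($\sigma/\mu^2$) is dimensionally inconsistent; the variance form is the
classical gliding-box definition and matches the binomial closed form
$\lambda \approx (1-p)/(np)$ for Bernoulli occupancy, which the tests
verify. The scalar reported per tumor is the mean over the box-count
scale range.

**Interface width.** For each patch scale $s$, every $s\times s$ window on
the (φ, z) grid (periodic in φ) contributes the variance of $r$ about the
window mean; $W(s)$ is the square root of the window-averaged variance.
Windows containing interpolated (unobserved) bins are excluded — the
filled polar caps are artificially smooth and would bias the small-scale
width down. $\alpha_{loc}$ is the log–log slope of $W(s)$ at small $s$,
with the small-$s$ regime separated from the saturation plateau by a
two-segment piecewise-linear fit in log–log coordinates; scales below 4
grid cells are excluded from the fit because bin-level discretization
steepens them. $W_{sat}$ is the mean of $W$ over the plateau (fallback:
top quartile of scales, flagged). The global roughness exponent $\alpha$
is the cohort-level slope of $\log W_{sat}$ against $\log\langle R\rangle$.

## Regularity measures

$S_R = 6\sqrt{\pi}\,TV/TS^{3/2}$ compares the tumor volume with the volume
of the sphere having the tumor's surface area; 1 for a sphere, smaller for
rough or elongated shapes, scale invariant. $S_F = S_R^{2/3}$ is carried
along for comparability with the surface-factor convention. $S_C$ applies
the same ratio to the contrast-enhancing region with *all* boundary
components (cavity walls included) in $TS_C$, so a necrotic core pushes
$S_C$ below $S_R$; the ratio $S_C/S_R$ is the discriminator, equal to 1
for solid lesions by construction. Elongation is corrected through the
PCA ellipsoid of the interface points: $f_{shape}$ is the ellipsoid volume
over the volume of the equal-area sphere (ellipsoid area by the Thomsen
approximation, $p = 1.6075$, max error ~1%), and $S_R^* = S_R/f_{shape}$.
Fractional anisotropy of the axes quantifies elongation on [0, 1].

Surface areas come from the coarea formula: the voxel-integrated gradient
magnitude of a Gaussian-smoothed (σ = 1.5 voxel) indicator. Raw voxel-face
counting overestimates areas by ~1.5× and would make $S_R \approx 0.55$
for a perfect sphere; the coarea estimator is within ~1% on spheres and
naturally sums inner and outer boundary components for $S_C$.

PCA axes use the uniform-shell convention $\lambda_i = \sqrt{3\,e_i}$
(covariance eigenvalues $e_i$), exact for spherical shells. Note that a
voxelized ellipsoid boundary samples the surface by *area*, which
concentrates points near the equator and compresses the apparent axis
ratio (a 2:1:1 ellipsoid reads ~1.7:1:1); the affine image of uniform
sphere directions reproduces 2:1:1 exactly, and FA remains a faithful
monotone elongation index either way.

## Visibility graphs

The natural visibility graph links two samples of an ordered series iff
the straight segment between them passes strictly above every intermediate
sample; series are treated as non-periodic and consecutive samples are
always linked. The implementation is the $O(n^2)$ forward sweep that keeps
the maximal blocking slope, verified edge-for-edge against a brute-force
all-pairs oracle. The degree-distribution exponent γ is fitted on the
log–log normalized histogram for $4 \le k < 20$: above ~20 the finite
series size truncates $P(k)$ abruptly, and below the distribution mode
(~3–4) $P(k)$ is still rising and would flatten the slope. The windowed
degree deviation $W_k(\phi)$ averages the within-window standard deviation
of degrees over all contiguous windows of angular span φ (population SD at
$\phi = 2\pi$); its small-span slope is the local variance exponent $a$,
using the same crossover detector as the interface width. γ orders series
by smoothness — across fractional Brownian fixtures its magnitude
decreases monotonically with the Hurst exponent.

## Multifractal analysis

**1D partition function.** The profile $R_i = \sum_{k\le i}(r_k - \langle
r\rangle)$ is cut into $\lfloor N/s\rfloor$ disjoint segments; box
"probabilities" are the profile increments and
$Z_q(s) = \sum_v |p_s(v)|^q$. $\tau(q)$ is the per-q slope of $\log Z_q$
vs $\log s$, $D(q) = \tau(q)/(q-1)$ with the $q=1$ information dimension
taken as the flanking-difference derivative of τ on the q grid, and
$h(q) = (\tau(q)+1)/q$. Absolute values are used throughout, so odd
moments are well defined for signed series. Mean-centering is the correct
convention for interface radius series, but it destroys the negative-q
structure of a *positive multiplicative measure* (masses near the mean
produce near-zero centered increments); `center = FALSE` analyzes such
measures on their raw masses, under which the binomial cascade reproduces
its closed form $\tau(q) = -\log_2(p^q + (1-p)^q)$ to machine precision —
including $D(2) = 0.786$ and the entropy value $D(1) = 0.881$ at
$p = 0.3$.

**2D MF-DFA.** The (φ, z) radius grid is mean-centered and doubly
cumulated; disjoint $s\times s$ segments (averaged over all four corner
anchors so trailing margins are used) are detrended by a least-squares
plane (order configurable); $F_q(s)$ is the q-generalized mean of the
per-segment RMS residual, with the geometric mean at $q = 0$; $h_2(q)$ is
the per-q slope, $\tau_2(q) = q h_2(q) - 2$, and $D_2(q)$ follows as in
1D. Default scales run from 6 to a quarter of the grid; the q grid
defaults to $[-4, 4]$.

Two finite-size facts are worth knowing. First, estimated τ(q) curves on
*signed noisy* series are concave only up to fit noise (violations up to
~0.05 at extreme q); the Legendre structure is exact on measure fixtures.
Second, strongly correlated monofractal surfaces show the well-documented
spurious multifractality at negative q; segments smaller than ~10 cells
underresolve the plane fit and inflate negative moments, so monofractal
reference checks use a scale ladder starting at 10. On a stationary
long-range-correlated Gaussian field (spectral exponent β = 1) at
$256^2$, the seed-averaged $h_2(q)$ is then flat to within 0.1 across
$q \in [-4, 4]$.

## The synthetic generator: what it emulates, and what it does not

All validation inputs are generated with known ground truth:

- **Rough tumors**: star-convex surfaces $r(\phi, z) = R\,[1 + a f(\phi,
  z)]$ with $f$ a zero-mean unit-variance self-affine Gaussian field of
  Hurst exponent $H$, synthesized spectrally (power $\propto
  k^{-(2H+2)}$) on a periodic (φ, w) grid with $w = (1+\cos\theta)/2$ —
  the same index space the cylindrical analysis grid uses, so generated
  and measured Hurst exponents are directly comparable. The synthesis
  grid (1024 × 512) is several times finer than any analysis grid so the
  surface carries sub-bin power like a real self-affine surface. Axis
  ratios produce ellipsoidal deformation; `core_fraction` carves a
  concentric contrast-free cavity. A voxel belongs to the tumor iff its
  center lies inside the analytic radius field.
- **Amplitude default 0.2** of the mean radius: cohort tables in the MRI
  literature put saturated interface widths at 15–25% of the mean tumor
  radius, and 0.2 sits mid-range. Validation tumors use $R = 40$ voxels
  on $152^3$ grids — large enough that the bin scale (~2.6 voxels) leaves
  a usable scaling window, small enough that thirty of them fit in a few
  minutes of test budget.
- **Series**: exact fractional Gaussian noise / fractional Brownian
  motion by Davies–Harte circulant embedding; deterministic binomial
  cascades with closed-form spectra; Koch curves for the box-counting
  oracle.
- **Mixtures**: per-voxel Gaussian intensity mixtures rounded to integer
  digital levels, with the class map as ground truth.

All randomness flows through explicit integer seeds and a local RNG that
never touches the global `.Random.seed`.

What the generator does *not* emulate: MRI physics (bias fields, partial
volume, Rician noise), non-star-convex topologies, anisotropic voxel
spacing beyond a scale factor, or scanner-specific resolution. Passing
tests therefore demonstrate estimator correctness on geometry with known
statistical structure — not robustness to acquisition artifacts.

## Known limitations

- **Small-Hurst recovery is bias-limited.** A surface with $H = 0.3$
  carries most of its variance below the voxel scale; the voxelized,
  smoothed measurement is effectively low-passed and reads
  $\alpha_{loc} \approx 0.47$ instead of 0.3. The bias shrinks with $H$
  (≈ +0.10 at $H=0.5$, ≈ +0.02 at $H=0.7$) and with tumor size, but no
  measurement choice we tested (bin statistic, refinement width, grid
  resolution) removes it at realistic sizes.
- **Box counting of self-affine surfaces is pre-asymptotic.** $d_F = 3-H$
  holds only where the fluctuation amplitude exceeds the box size across
  the whole fit range; outside that regime box counting drifts toward 2.
  Even densely sampled analytic surfaces at realistic amplitudes return
  $d_F \approx 2.40/2.31/2.17$ for $H = 0.3/0.5/0.7$ rather than
  2.7/2.5/2.3. Consequently the measured Family–Vicsek sum on synthetic
  rough spheres plateaus near 2.7–2.8 rather than 3.0. Empirical cohorts
  with $\alpha_{loc} \approx 0.7$–0.85 sit in the regime where the bias
  is small, which is consistent with sums of 2.9–3.0 reported for real
  glioma data.
- **Per-realization width scatter.** With a $k^{-(2H+2)}$ spectrum a few
  low-k modes dominate the saturated width, so the *realized* $W_{sat}$
  of independent tumors scatters strongly around $aR$. Cohort-level
  exponent checks therefore construct cohorts that share one roughness
  realization and vary size and amplitude.
- The polar caps of the cylindrical grid are interpolated, not observed;
  all width statistics exclude them, but the 2D MF-DFA necessarily
  includes them as smooth regions.
- Visibility-graph exponents from short slice series (a few hundred
  samples) are strongly finite-size limited; γ magnitudes are comparable
  *within* a cohort analyzed at one resolution, not across resolutions.
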