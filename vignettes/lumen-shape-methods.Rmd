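---
title: "Methods: lumen morphometry and the 2D vertex model"
author: "lumenmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lumen morphometry and the 2D vertex model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices behind
`lumenmorph`, in the order a user meets them: contour smoothing, 3D surface
metrics, cross-section metrics, the vertex model, the statistics, and the
phantom generators that everything is validated against.

## Contour smoothing

Slice boundaries are closed planar curves. Each is parameterized by
cumulative contour length normalized to $[0, 2\pi)$, and each coordinate is
fit by least squares to a truncated Fourier series
$x(s) = a_0 + \sum_{m=1}^{M} a_m \cos ms + b_m \sin ms$ with $M \le 15$.
A single order is selected for both coordinates by a Gaussian BIC,
$\sum_{\text{coords}} [\,n \log(\mathrm{RSS}/n) + (2M+1)\log n\,]$, with
ties within $10^{-9}$ broken toward the lower order. Selecting one joint
order (rather than one per coordinate) keeps the curve representation
coherent; this is a design choice, not a mathematical necessity.

Two numerical details matter in practice:

* **Parameter pre-smoothing.** The arc-length parameter is computed from a
  5-point circular moving average of the polygon (the fitted points are not
  smoothed). Without this, independent point noise random-walks into the
  cumulative chord length and masquerades as genuine low-order harmonics:
  on a circle with 2% radial noise, BIC then selects order ~5 instead of 1.
  With pre-smoothing the modal selected order on that benchmark is 1 in
  100/100 seeds (see `test-contour_fitting.R`).
* **Exactness limits.** A curve built from an order-$M$ series is recovered
  *exactly* only when its speed is constant (e.g. circles): the contour-
  length parameterization otherwise reparameterizes the curve, so small
  residuals ($\sim 10^{-4}$ of variance at order 15 for strongly non-uniform
  speed) are intrinsic, not fitting error.

Curvature comes from the analytic series derivatives,
$k = (x'y'' - y'x'')/(x'^2+y'^2)^{3/2}$, which is parameterization-invariant;
area and perimeter come from Green's-theorem and arc-length quadrature on a
dense periodic grid (trapezoid rule, spectrally accurate here). Contours are
re-oriented counterclockwise on ingest so that positive curvature always
means bending toward the enclosed region.

## 3D surface metrics

A `voxel_surface` is a single 6-connected component not touching the array
border, with anisotropic voxel spacing applied *before* any fitting, so all
geometry is in physical units (µm).

* **Boundary extraction** uses connected-component labelling and ordered
  outer-boundary tracing (8-connectivity, pixel centers, 0-based indices).
  Pixel-center chains trace the centers of boundary voxels, half a voxel
  inside the physical boundary; `smooth_stack` therefore offsets each chain
  outward by half a voxel along the local normal before fitting. This
  removes a systematic shrink bias of several percent in volume at 0.5 µm
  spacing (the sphere phantom lands within ~0.1–0.2% of the analytic volume
  with the offset; see the acceptance script's `sphere_volume_rel_error_pct`).
* **Volume** is the sum of smoothed XY-contour areas times the z-spacing.
* **Surface area** is a banded quadrature: each smoothed contour is
  resampled at 256 angles about its centroid (assuming star-shaped slices,
  true for all phantoms and for typical lumens), consecutive rings are
  joined by a triangle strip, and the first and last contours close the
  surface as flat caps. A 3-point binomial filter across slices damps
  independent fit wiggle that would otherwise inflate every band's slant.
* **Mean curvature.** At each location where a smoothed XY contour (fixed z)
  and a smoothed YZ contour (fixed x) pass within one voxel diagonal, the
  surface normal $u$ is estimated as the normalized cross product of the two
  section tangents, each section contributes a normal curvature
  $k_n = k\,N \cdot u$ (implemented as the projection of the curve's
  curvature vector onto $u$), and $H$ is the mean of the two. By Euler's
  theorem this is exact when the two tangent directions are orthogonal
  (always true on a sphere, approximately true elsewhere), which is why the
  sphere recovers $H = 1/r$ to ~1% while the ellipsoid shows a ~7% median
  relative error away from its poles. Frames with near-parallel tangents
  (cross-product norm < 0.1) are skipped and counted. $u$ is oriented
  outward and the sign fixed so a sphere is positive (convex) and regions
  bowed into the enclosed volume are negative (concave).
* **Fraction concave** is the unweighted fraction of sampled frames with
  $H < 0$; optional per-frame weights are accepted for an area-weighted
  variant.
* **Sphericity** $\Psi = \pi^{1/3}(6V)^{2/3}/A$ is clamped at 1 (and
  flagged) when numerical error pushes it above; the estimated radius is
  $r = (3V/4\pi)^{1/3}$.

The XY/YZ section pair is used exactly as stated — no XZ fallback; geometry
degenerate for both sections simply yields no frame there.

## Cross-section metrics

Solidity ($a/A_{\text{hull}}$), IPQ ($4\pi a/p^2$), mean cell thickness
$2(A_b - A_a)/(P_b + P_a)$ (which collapses to the ring width $R-r$ on any
concentric annulus), and the normalized lumen radius
$r_{\text{norm}} = r_l/(r_s - r_l)$ with $r = \sqrt{A/\pi}$. Convex hulls
are taken over dense samplings ($\ge 256$ points) of smoothed contours.
Self-intersecting polygons are rejected (the check is $O(n^2)$ and can be
disabled for dense contours known to be simple).

## The vertex model

An $N$-cell spheroid is a 6N-vector: apical and basal vertex positions plus
one signed apical and one signed basal arc curvature per cell. Cell $i$ is
bounded by the basal arc $b_i \to b_{i+1}$, two straight laterals, and the
apical arc $a_i \to a_{i+1}$. All lengths are in units of $\sqrt{A_0}$ and
areas in units of $A_0$; the energy is

$$\tilde H = -\tilde p\,A_L + \sum_i \left[(A_i - 1)^2 +
k\left((l_{a,i} - \tilde l_a)^2 + (l_{b,i} - \tilde l_b)^2 +
l_{l,i}^2\right)\right]$$

with one lateral term per cell (each lateral belongs to exactly one
summand). The cell area constraint is soft: the quadratic term *is* the
area regulation. Arc lengths follow $l = (2/|\kappa|)\arcsin(|\kappa|d/2)$
from the chord $d$, with a Taylor fallback to $d$ for $|\kappa|d < 10^{-6}$;
cell areas are the vertex-quad shoelace area plus/minus circular-segment
areas. The sign convention — positive curvature bulges to the right of the
counterclockwise traversal, i.e. away from the enclosed interior — makes the
stated initial apical curvatures in $[1, 2]$ mean outward-bowed arcs, and
makes the initial basal curvature $1/2$ the curvature of the radius-2 basal
circle.

**Initialization.** Basal vertices evenly spaced on a circle of radius 2;
apical vertices i.i.d. uniform in the unit disk, relabelled in
counterclockwise angular order about their centroid (a relabelling of an
exchangeable draw — the point set's distribution is unchanged, but cell
adjacency becomes well defined); apical curvatures uniform on $[1, 2]$.
The draw is rejection-sampled until the apical arcs form a simple loop, so
the physicality constraint below is active from the first descent step.

**Minimization.** "Stochastic gradient descent to within 0.01 of a local
minimum" is operationalized as: central finite-difference gradient
($h = 10^{-6}$), a seeded Gaussian perturbation of the descent direction
decaying as $1/\sqrt{\text{iter}}$ (scale 0.05), fixed step $10^{-3}$ with
backtracking so the energy never increases, and rejection of physically
invalid proposals. Convergence is certified by a two-part test: a full pass
moves every coordinate by less than $10^{-3}$, *and* no single-coordinate
move of 0.01 lowers the energy (if one does, the optimizer takes it and
continues — a cheap saddle escape). The distance-to-minimizer criterion is
not directly observable; this pair is a conservative operational proxy, and
a finite-difference gradient oracle in the tests verifies near-stationarity
against the local curvature scale.

**Physicality.** The Hamiltonian does not forbid overlapping cells, so
states are checked geometrically: the apical and basal arc loops must be
simple and must not cross each other, and laterals must not cross. The
check runs on arc polylines sampled at a length-proportional power-of-two
count (~32 points per unit arc length) with two-level bounding-box pruning.
The power-of-two rule makes the verdict stable under division — daughters
sample exactly the parent's positions — which matters because a flipped
verdict would silently disable the constraint for the following
minimization. Arcs are clamped just below the semicircle limit inside the
optimizer (a smooth quadratic penalty pushes back), while user-facing
geometry treats $|\kappa| d/2 > 1$ as an error.

**Division and growth.** The cell with the largest energy summand (pressure
excluded, ties to the lowest index) is split by inserting new vertices at
the midpoints of its apical and basal arcs; daughters inherit the parent's
curvatures, so lumen area, all cell areas and all boundary lengths are
conserved to $10^{-9}$ at the instant of division (tested). Growth
alternates minimize/divide from 3 to 10 cells.

**Parameters.** $k = 2.0$ and $\tilde l_a = 0.6$ are the data-style
estimates used for the wild-type condition; the Rab11a-OE preset raises
$\tilde l_a$ to 0.8 and the Cldn-qKO preset raises it to 1.0 with tenfold
lower pressure. Pressure and $\tilde l_b$ are free parameters of the model,
stated to be chosen to agree with data; the shipped calibration fixes
$\tilde p_{\mathrm{WT}} = 0.2$, $\tilde l_b = 1.0$ from a coarse one-time
scan as the setting where the leaky-junction condition reproduces the
observed ordering — larger lumen cross-section and basal length than wild
type at matched cell number, with a moderate solidity change. The
stringency estimator $k \approx \sigma_A^2/(\sigma_{l_a}^2 A_0)$ follows
from the Boltzmann fluctuation relations
$\sigma_A^2 = k_BT/2k_A$, $\sigma_{l_a}^2 = k_BT/2k_l$ under
independence of area and apical-length fluctuations; unbiased sample
variances are used, and the tests recover $k$ within 10% at $n = 10^4$.

Simulation sizes: growth runs use 25 seeds per condition in the acceptance
script (matching the replicate count the trends are defined over) and 8–10
seeds in unit tests and analysis drivers.

## Statistics

* **2D Kolmogorov–Smirnov** (Fasano–Franceschini): the statistic is the
  largest difference in empirical quadrant fractions over the four quadrant
  orientations anchored at every data point, averaged over anchoring in
  either sample; points on an anchor's axes count in no quadrant. The
  p-value uses the asymptotic Kolmogorov form with effective size
  $\sqrt{n_1 n_2/(n_1+n_2)}$ and the correlation adjustment
  $\sqrt{1 - \bar r^2}$. Below $n = 20$ per sample the p-value is flagged
  approximate rather than permutation-corrected — no permutation procedure
  is prescribed, and the asymptotic form's type-I error at $n = 100$ is
  verified to sit in $[0.03, 0.07]$ at $\alpha = 0.05$ by simulation.
* **Exact matching** on the integer covariate (cells per cross-section):
  strata missing any group are dropped; within retained strata the
  reference group (first listed — wild type by convention) keeps weight 1
  and each other group is weighted $n_{\text{ref}}/n_g$, so weighted
  stratum frequencies match the reference exactly. A coarsening width is
  available but off by default (pure exact matching on integers).
* **Weighted Welch**: weighted means/variances with effective sample size
  $(\sum w)^2/\sum w^2$ and Welch–Satterthwaite degrees of freedom on the
  weighted quantities; with unit weights this reproduces `t.test()` to
  $10^{-10}$ (tested on 100 random datasets).

## Phantoms: what they do and do not emulate

The generators provide voxelized spheres, ellipsoids and dimpled spheres
with analytic $V$, $A$ and mean curvature (the implicit-surface
$H = (\mathrm{tr}\,\mathcal{H} - n^\top \mathcal{H} n)/(2|\nabla F|)$
oracle is invariant to monotone rescaling of $F$), planar circles,
ellipses, stars, plus-signs and squares with closed-form or quadrature
truths, annulus cross-sections, and Boltzmann-distributed per-cell samples.
Scales mirror the biology (radii ~2–15 µm, spacing 0.1–0.5 µm) so stated
tolerances are meaningful at realistic discretization. The dimpled sphere's
crater sits on the +y axis, in-plane for both section families; a crater at
a z-pole would make XY slices annular, and outer-boundary extraction would
never see the concave wall — a real limitation of the two-section
construction for strongly non-star-shaped surfaces, inherited from the
method itself.

What the phantoms deliberately do not emulate: microscope point-spread
functions, shot noise, segmentation errors beyond independent
boundary-voxel flips, multi-lumen topologies, and surfaces that are not
star-shaped per slice. Passing the phantom suite therefore demonstrates
correctness of the geometry and estimators at realistic discretization, not
robustness to realistic imaging artefacts.

## Known limitations

* The two-section mean-curvature estimator degrades where the two section
  tangents are far from orthogonal (high-curvature poles of elongated
  bodies) and where slices are annular rather than simply connected.
* Surface-area quadrature assumes star-shaped slices about their centroid.
* The vertex model has no neighbor exchanges, no cell death, and no
  3D effects; pressure and basal rest length are calibrated, not measured.
* The 2D KS p-value is asymptotic; very small samples get a flag, not an
  exact test.
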