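---
title: "Methods: models, parameters and design choices in mechanophen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mechanophen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanophen)
```

mechanophen quantifies the mechanical phenotype of single tumor cells and
multicellular clusters from fluorescence microscopy: the traction forces they
exert on soft substrates, the anisotropy of those forces, their shape and
deformability, their wetting geometry on a substrate, their migration, and —
on the molecular side — a per-cell stemness signature score from single-cell
expression data. Every pipeline input can be produced by the bundled
synthetic-microscopy generators with exact ground truth, so each analysis
stage is testable end to end without any external data. This vignette
documents the models, the tunable parameters with their units and defaults,
the numerical choices, and the places where the design was genuinely open.

## Traction force microscopy

### Forward model

The substrate is a linear-elastic half-space (Boussinesq approximation, valid
for gels much thicker than the displacement decay length). A tangential
traction field $\mathbf{T}(\mathbf{x})$ (Pa) on the surface produces an
in-plane surface displacement

$$\mathbf{u}(\mathbf{x}) = \int G(\mathbf{x}-\mathbf{x}')\,
  \mathbf{T}(\mathbf{x}')\, dA',\qquad
  G(\mathbf{r}) = \frac{1+\nu}{\pi E r^3}
  \begin{pmatrix} (1-\nu)r^2 + \nu x^2 & \nu x y \\
                  \nu x y & (1-\nu)r^2 + \nu y^2 \end{pmatrix},$$

with Young's modulus $E$ (0.5–30 kPa for the polyacrylamide substrates this
package targets) and Poisson ratio $\nu$. Polyacrylamide is nearly
incompressible, so $\nu = 0.5$ is the default; it is configurable because the
source protocols never state it. `forward_displacement()` evaluates this
convolution two ways: a spectral method using the Fourier-domain tensor
$G(\mathbf{k})$ (zero-padded by one full field size to suppress periodic
wrap-around — a factor-4 memory/time cost bought for accuracy), and a
direct real-space summation (`method = "direct_sum"`, compiled) that
integrates the singular self-cell on a 16×16 subgrid. The two are independent
implementations and agree to a few percent on interior nodes; the direct sum
is the oracle in the test suite.

### PIV

`piv_displacement()` estimates bead displacements with square interrogation
windows (default 32 px, overlap 0.5 — the standard configuration for bead
images of this kind). Correlation is zero-mean, FFT-based, zero-padded to
twice the window so it is non-circular, and normalized by the per-lag overlap
count, which removes the classical bias of zero-padded correlations toward
zero lag. The peak is refined with a three-point Gaussian fit (parabolic
fallback when a neighbor is non-positive). Vectors fail validation when the
first-to-second peak ratio drops below 1.05 or when they deviate from the
3×3 local median by more than 2 px; failed vectors are replaced by the local
median rather than dropped, and flagged in `$valid`.

A single correlation pass measures the *window-averaged* displacement, which
on smoothly varying elastic fields biases each vector by roughly
$w^2 \nabla^2 u / 24$ (about 0.1 px for the bundled synthetic fields). The
default therefore runs three image-deformation passes: the deformed image is
warped by the current displacement estimate (Catmull–Rom bicubic sampling for
both the image and the coarse field) and the residual is re-correlated.
Windows whose warp had to sample outside the image keep their previous
estimate instead of absorbing a corrupted residual.

### Inverse problem

`fttc_tractions()` inverts the forward operator in the Fourier domain with
Tikhonov regularization, per wavevector
$\hat{\mathbf{t}} = (G^\top G + \lambda^2 P)^{-1} G^\top \hat{\mathbf{u}}$.
The zero-frequency traction is set to zero: a rigid substrate translation is
unobservable, which is equivalent to the net-force-free convention. The
reported traction is the stress exerted *by the cell on the gel*. Displacement
gaps (invalid PIV vectors) are filled by neighborhood averaging before the
FFT, and the field is reflect-padded by half its size per side (disable with
`pad = FALSE` for exactness tests; the equivariance tests use the unpadded
path).

Two penalty shapes are available. The default, $P = I$ (zeroth order) with
$\lambda = 10^{-9} E$, is essentially unregularized and appropriate for clean,
densely sampled displacement fields. On PIV-resolution grids the inverse
operator amplifies white displacement noise by $\sim E k$, and because
$G \sim 1/k$ a zeroth-order penalty strong enough to control that noise also
attenuates the signal band. The first-order option (`reg_order = 1`,
$P = k^2 I$, a gradient penalty) leaves low-frequency amplitude untouched
while cutting the high-frequency amplification, and is what the round-trip
validation uses. Its $\lambda$ is chosen automatically by
`fttc_select_lambda()`: an L-curve in the Fourier domain whose corner is the
positive-curvature local maximum with the largest residual — the macroscopic
knee where regularization starts removing signal, as opposed to the small
knee where it starts absorbing noise. No quantity in that selection involves
ground truth.

### Summaries

`mean_traction()` is the mean of $|\mathbf{T}|$ over the nodes inside a mask
(a node belongs to a pixel mask iff its center pixel is labeled — no
partial-area weighting). `dipole_matrix()` computes the first moment
$M_{ij} = \sum (x_i - o_i) T_j \, dA$ over the masked nodes, symmetrizes it
(the discrete raw moment need not be symmetric), and `dipole_anisotropy()`
reports eigenvalues ordered by magnitude and the anisotropy
$M_\delta = |\lambda_1| / |\lambda_2| \ge 1$. Absolute values are used
because contractile dipoles have negative eigenvalues. The default origin is
the traction-weighted center, which makes the moment robust to slight force
imbalance; the mask centroid is available. When the minor eigenvalue falls
below $10^{-6}$ of the major one the ratio is capped at $10^6$ and flagged;
a zero matrix yields `NA` with a flag.

## Shape and deformability

For a closed contour with area $A$ and perimeter $P$:

* **roundness** $= 4A / (\pi \cdot \text{major axis}^2)$, the major axis
  taken from the ellipse with the same second central moments — the
  ImageJ/Fiji "roundness" descriptor (chosen over circularity because that is
  the descriptor the shape-analysis protocol names). Exact polygon moments
  are used for contours; pixel moments plus the $1/12$ per-pixel variance
  correction for masks.
* **deformation** $= 1 - 2\sqrt{\pi A}/P$, zero exactly for a circle
  (isoperimetric equality) and positive otherwise.
* **porosity** $=$ convex-hull area $/ A$, the deformability-cytometry
  contour-quality measure (the protocols use the word without a formula; the
  hull-ratio convention is the established one).

Perimeters of rasterized objects come from sub-pixel marching-squares
contours (`mask_contours()`, the 0.5 level of the binary mask) because
pixel-edge counting overestimates $P$ and biases deformation upward; exact
polygons bypass rasterization entirely.

`rtdc_gate()` passes a contour iff porosity $\le 1.05$ **and** area
$\in [150, 350]\ \mu m^2$. The bounds are inclusive — the protocols say
"outside the range", leaving endpoints ambiguous, and inclusivity is the
measure-zero-safe reading. Pass/fail is conjunctive and order-free; only the
per-contour failure *reason* uses porosity-first precedence, and the report
counts satisfy `n_pass + n_fail_porosity + n_fail_area = n_input`.

## Wetting geometry

A cluster on a substrate is modeled as a spherical cap of contact radius $R$
and height $H$, giving $R_{sphere} = (R^2 + H^2) / (2H)$ and contact angle
$\theta = \arcsin(R / R_{sphere})$ (wet) or
$\alpha = 180^\circ - \arcsin(R / R_{sphere})$ (dewet). Cap geometry
guarantees $R \le R_{sphere}$, the regimes are assigned by comparing $H$
with $R_{sphere}$ (the protocols assign formulas to wet and dewet clusters
without stating the rule; this geometric criterion is continuous, both
branches giving 90° at the hemisphere). Angles are reported in degrees.

`measure_cluster()` extracts $R$ as the equivalent-circle radius
$\sqrt{A_{basal}/\pi}$ of the thresholded basal slice (robust to boundary
noise, unlike a maximum chord) and $H$ from the topmost occupied slice with a
half-z-step midpoint correction. For dewet caps the widest section lies above
the substrate, so the widest-plane radius is reported alongside the basal
one; the basal value feeds the angle formulas.

## Segmentation and intensities

`segment_objects()` thresholds (Otsu global by default, locally adaptive mean
over a 51-px block minus an offset as the alternative — the protocols name
"level and locally adaptive thresholding" without parameters), then applies
morphological closing (disk radius 2 px), hole filling, and small-object
removal (20 µm² default). Connectivity defaults to 8. All of these are
configurable precisely because none is stated by the protocols. Manual
quality control ("incorrectly segmented objects were discarded") is replaced
by automatic flags: border-touching labels and area outliers beyond 3 MAD.

`cytoplasm_mask()` multiplies the inverted nucleus mask into the cell mask;
`yap_ratio()` is the nuclear over cytoplasmic mean intensity, `NA` with a
warning when the cytoplasmic mean is zero. `mean_intensity()` subtracts a
background that defaults to the median of the complement of the 2-px dilated
mask (the protocols say only that values were background-subtracted);
negative results clamp to zero with a warning unless negatives are allowed.
Both ratios and background-subtracted means are invariant under positive
rescaling of the image when the background is estimated from the same image.
`plane_intensity_profile()` resolves plane offsets (e.g. 0, 5, 10, 15 µm
above a monolayer) to nearest slices and averages the masked per-plane means.

## Tracking

`link_centroids()` links by proximity with greedy globally-nearest-pair
assignment per frame transition (mutually closest pairs first, ties to the
smaller track id), a 30 µm default link ceiling, and no gap closing (none is
described by the protocols). Optimal assignment was deliberately not used:
for the sparse scenes in scope greedy linking is exact, simpler, and easier
to reason about. `velocity()` is accumulated path length over total elapsed
time — a circular path has positive velocity. Manual discarding of unreliable
tracks is replaced by an explicit rule: trajectories shorter than 5 frames
are flagged and excluded from summaries.

## Expression scoring

`normalize_expression()` scales cells to the median library size and applies
`log1p`. `smooth_expression()` is a *declared simplified stand-in* for
kernel-based imputation (the full adaptive-kernel algorithm with automatic
diffusion time is out of scope): cells are embedded on 20 leading principal
components, a symmetric adaptive-bandwidth kNN affinity (bandwidth = distance
to the k-th neighbor, union symmetrization, k = 15 default) is
Sinkhorn-normalized to a doubly stochastic operator, and expression is
diffused `t` steps (default 2). Double stochasticity gives both a
row-stochastic diffusion reading and exact conservation of per-gene total
mass across cells; on disconnected cell groups the diffusion converges to
within-group means without cross-talk.

`signature_score()` is the arithmetic per-cell mean of the signature genes
(default the five-gene stemness list BCL11B, AXIN2, LGR5, ASCL2, LRIG1).
`classify_lgr5()` labels a cell LGR5+ iff its score is *strictly above* the
75th percentile computed with the linear-interpolation definition (R type 7)
— both the tie rule and the percentile definition are conventions the
protocols leave open. All-equal scores label nothing and flag the result
degenerate; a crude histogram-valley bimodality check flags score
distributions where the two populations cannot be distinguished, surfacing
(rather than silently applying) the exclusion rule used for undistinguishable
patient datasets. `group_mean_expression()` reports per-gene group means with
difference (LGR5+ minus LGR5−) and ratio columns; with the default ERM genes
(EZR, RDX, MSN) a negative EZR difference reproduces the expected
anticorrelation between stemness and membrane-to-cortex attachment.

## The synthetic generators: what they emulate, and what not

* `gen_bead_image_pair()` — elastic-substrate TFM image pairs: beads at
  0.03 beads/µm² (the bead concentration the protocols give is a weight
  fraction; this surface density is the declared imaging-plane equivalent),
  rendered as isotropic Gaussians of σ = 1.5 px (0.2 µm beads are below the
  diffraction limit), displaced by the forward elastic solution interpolated
  at each bead, additive Gaussian read noise (σ = 2 by default) and optional
  Poisson shot noise. No microscope PSF model beyond the Gaussian, no bead
  polydispersity, no focal drift: a green TFM test establishes numerical
  correctness of the displacement/traction chain, not robustness to real
  optics.
* `gen_cell_scene()` — flat-intensity disks/ellipses with exact masks;
  real cells have textured interiors and soft edges, so segmentation
  accuracy numbers from these scenes are upper bounds.
* `gen_cluster_stack()` — ideal spherical caps; real clusters deviate from
  sphericity, which is precisely why the contact-angle formulas are applied
  to measured $(R, H)$ rather than fitted spheres.
* `gen_contours()` — circles, ellipses and notched stars with dense-polygon
  ground truth; the notch family (depth 0.4–0.85, angular width 0.08–0.3
  rad) straddles the 1.05 porosity gate.
* `gen_tracks()` — stationary, linear and random-walk motion with
  closed-form velocities; no mitosis, merging or detection dropout.
* `gen_expression()` — negative-binomial counts (dispersion `noise`,
  default 0.3) with log-normal size factors (σ = 0.2), a planted LGR5-high
  fraction (default 0.25) with 3-fold signature elevation, and an EZR
  reduction by `erm_anticorrelation` (RDX/MSN at square-root strength,
  reflecting the weaker, patient-subset anticorrelation of those two genes).
  No generative model is stated for the original droplet-based counts; NB
  with size factors is the field-standard stand-in.

All generators are deterministic under a fixed seed.

## Known limitations

* Half-space elasticity only: no finite-gel-thickness correction, no 2.5-D
  traction recovery.
* The diffusion smoother is not the full adaptive-kernel imputation
  algorithm, and conclusions about imputation quality do not transfer.
* Conversion of deformation to an apparent elastic modulus requires external
  lookup tables and is deliberately out of scope.
* The greedy linker has no occlusion or division handling.
* TIFF I/O is unavailable in the target environment; all image exchange uses
  the documented CSV raster format.
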