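---
title: "Validating voxel microFE models of vertebral bodies against DVC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating voxel microFE models of vertebral bodies against DVC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model and the validation question

A voxel microFE model converts every bone voxel of a segmented micro-CT
image into one 8-node hexahedral finite element with homogeneous,
isotropic, linear elastic material (tissue modulus $E_t$, Poisson's ratio
$\nu = 0.3$). The model is driven purely by Dirichlet boundary
conditions: every node on the extreme axial node planes (the single top
and bottom voxel-corner layers) is constrained in all three components to
the displacement measured there by digital volume correlation (DVC), and
the interior is solved. Because the problem is linear with displacement
boundary conditions, the displacement solution is independent of $E_t$
and every reaction force is exactly proportional to it — two facts this
package leans on heavily (the modulus back-calculation is a closed-form
scale, and force linearity is a solver invariant tested to $10^{-8}$).

The validation question is whether such a deliberately simple model
predicts *local* displacements across the vertebral body. The workflow
(implemented in `run_validation()`):

1. mask the specimen (`build_mask()`), pick a segmentation threshold
   (`suggest_threshold()`), segment and keep the largest face-connected
   component (`segment()`, `connectivity_filter()`);
2. crop the middle 50% of the height for the model (`crop_fraction()`),
   compute BV/TV, and label cortical vs trabecular bone
   (`split_cortical_trabecular()`);
3. register the preloaded/loaded image pair (`register_volumes()`) on a
   grid with nodal spacing `ns`;
4. mesh (`build_mesh()`), impose DVC boundary conditions
   (`apply_boundary_conditions()`), solve (`solve_microfe()`), extract
   reactions and centroid strains;
5. compare predicted and measured displacements at the DVC grid nodes
   that fall inside bone elements and inside the middle 70% of the model
   height (`select_comparison_points()`), screen outliers once with
   Cook's distance at five times the mean (`cooks_filter()`), and report
   slope, intercept, $R^2$, RMSE against the 1:1 line, RMSE%, MaxError
   and Lin's concordance correlation (`regression_stats()`).

Axis and unit conventions: arrays are indexed `[z, y, x]` with z the
axial/compression direction; coordinate and displacement vectors are in
(x, y, z) order; lengths are micrometres, forces newtons, moduli
gigapascals. Conversions happen only in the I/O layer (MetaImage/NRRD
spacings are read as millimetres).

# Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `e_ref` / `e_t` | 12.0 | GPa | literature tissue modulus (microindentation); reference for back-calculation |
| `nu` | 0.3 | – | Poisson's ratio of bone tissue |
| `ns` | 48 | voxels | DVC nodal spacing; precision vs spatial resolution |
| `model_crop` | 0.5 | – | axial fraction of the specimen meshed |
| `comparison_fraction` | 0.7 | – | axial fraction of the mesh used for comparisons (limits boundary-condition influence) |
| `cooks_k` | 5 | – | outlier screen: remove points with $D_i \ge k \bar D$, applied once |
| `eps_p1y`, `eps_p3y` | +7200, −8000 | microstrain | tensile/compressive yield limits for vertebral trabecular tissue |
| `solver_tolerance` | 1e-8 | – | relative residual of the FE solve |
| `regularization_weight` | 0.05 | – | DVC smoothness weight (see below) |

On scaled-down problems (phantoms of 40–64 voxels per side) the default
`ns = 48` leaves too few grid nodes; the examples, tests and the
acceptance script use `ns = 8` on 40–48 voxel phantoms, preserving the
ratio of nodal spacing to specimen size rather than its absolute value.
These problem sizes are the package's own choice of test scale: large
enough that meshes have 10⁴–10⁵ elements and grids have well-supported
interior nodes, small enough that the whole suite runs on one CPU.

# The DVC solver

`register_volumes()` minimises the masked sum of squared grey differences
between the fixed image and the back-warped moved image,
$\sum_{mask} [F(x) - M(x + u(x))]^2 + \lambda_{eff}\,\|L u\|^2$,
where $u$ is trilinearly interpolated from the grid nodes and $L$ is the
axis-wise second-difference operator (rows only where both neighbours
exist, so *any affine nodal field has exactly zero penalty* — uniform
strains are not shrunk at the grid edge). Minimisation is Gauss–Newton
with step halving (the objective never increases across accepted steps)
over a coarse-to-fine block-mean image pyramid; there is no randomness
anywhere in the solver. $\lambda_{eff}$ rescales the user weight by
$\mathrm{tr}(J^TJ)/\mathrm{tr}(L^TL)$ at each level so the setting is
resolution-independent.

Three numerical choices deserve explanation:

* **Tricubic image sampling.** Trilinear interpolation of a blurred bone
  edge has a sub-voxel bias that pulls the optimum towards integer
  offsets; Catmull–Rom cubic convolution (`interpolation = "cubic"`, the
  default) removes most of it. The same option exists in `warp_volume()`
  when synthesising image pairs, because inverse-mapping trilinear
  warping followed by trilinear sampling double-interpolates (its default
  remains trilinear resampling).
* **Half-spacing refinement.** A piecewise-trilinear field fitted by
  least squares overshoots a smooth field at its nodes near the
  resolving limit (for a sinusoid of period $4\,NS$ the 1D projection
  factor is about 1.22). The finest level therefore re-estimates the
  field on an `ns/2` grid and reads out at the requested nodes
  (`refine_factor = 2`). The smoothness weight on the refined grid is
  multiplied by `refine_factor^4`: a smooth field's dimensionless second
  difference shrinks by the square of the spacing ratio, so the squared
  penalty needs the fourth power to exert the same physical pressure;
  without it the finer basis fits image noise.
* **Node support.** Grid nodes whose basis support contains few masked
  voxels are determined by the penalty, not the data. `dvc_node_support()`
  quantifies this (full interior support is $ns^3$), and DVC accuracy is
  only ever scored on nodes with at least a quarter of full support —
  the same logic by which displacement comparisons are restricted to
  nodes inside bone elements.

The `regularization_weight` default of 0.05 was selected with the
zero-strain protocol (`zero_strain_check()`: register two independent
noisy renderings of the same geometry and report the standard deviation
of nodal displacements and cell strains), which is also the recommended
way to re-tune it for other image material. Precision improves
monotonically with `ns`, reproducing the motivation for choosing a large
nodal spacing on real data.

# The FE solver

One 24×24 stiffness matrix (2×2×2 Gauss integration of the isotropic
elasticity tensor over a cube) is shared by all elements. Small models
(default at most 2000 elements) are assembled sparsely and solved
directly; larger models use Jacobi-preconditioned conjugate gradients
with a matrix-free element-by-element operator written in C++ — the
global matrix is never formed. Dirichlet conditions are eliminated by
constraint reduction. Strains are evaluated at element centroids from the
trilinear shape-function derivatives, with principal values from a
vectorised closed-form symmetric eigensolve; yielded-element counts are
per *element* (the centroid strain), which is the convention used
consistently here. Reaction forces are rows of $K u$ at constrained
nodes; AF is reported as the magnitude of the axial resultant over the
top plane, so compression is positive.

Verification is property-based: the patch test (affine surface
displacements reproduce the affine field in the interior to $10^{-8}$ on
random connected voxel blobs that do have free interior nodes), global
equilibrium of reactions, agreement with a dense direct oracle on small
meshes, the confined-compression closed form
$\sigma_{zz} = E(1-\nu)/((1+\nu)(1-2\nu))\,\varepsilon$, and exact
linearity of AF in $E_t$.

# What the phantom emulates — and what it does not

`generate_phantom()` builds an elliptic-cylinder cortical shell around a
gyroid lattice, with transverse semi-axes narrowed towards mid-height
(`waist`, default 6%) the way real vertebral bodies are waisted; without
some axial structure on the cortical surface the axial displacement
component would be poorly constrained by image content. The gyroid level
is calibrated by bisection so the realised BV/TV inside the envelope hits
the target within 0.005 (tested across the 0.30–0.50 range that covers
the porcine cohort the defaults mirror: BV/TV ≈ 0.33–0.49, trabecular
spacing ≈ 620 um, 39 um voxels). Grey rendering maps bone/background to
two levels, blurs with a Gaussian PSF and adds white Gaussian noise; all
randomness (lattice phase, noise) derives from one integer seed, so equal
seeds give bit-identical phantoms.

What it does *not* emulate: anatomically realistic vertebral shape,
marrow-driven grey inhomogeneity, beam hardening, ring artifacts, or any
correlated CT noise. Synthetically warped "loaded" images are background-
filled where content leaves the domain, so synthetic experiments trim the
registration mask away from the volume border
(`trim_mask_border()`) — the analogue of cropping scan-boundary artifacts
from real acquisitions. Consequently, passing the synthetic recovery
tests demonstrates correctness of the estimation machinery under known
ground truth, not robustness to every artifact of real scans.

# Degenerate inputs, ties and edge rules

* `connectivity_filter()` ties between equally large components go to the
  component first encountered in array order (deterministic).
* `suggest_threshold()` maximises between-class variance on a 256-bin
  masked histogram; the criterion plateaus across empty histogram gaps,
  and the middle of the maximal plateau is returned (so two separated
  equal modes give the midpoint). Constant grey values raise an error.
* `cooks_filter()` keeps everything when the fit is numerically perfect
  (the distances are 0/0); the screen is applied once, never iterated.
* Comparison points lying exactly on an element face belong to the
  element whose low corner is `floor(p / voxel_size)`.
* `crop_fraction()` keeps `round(f N)` slices starting at
  `floor((N - kept)/2)`, making slab indices reproducible.
* `split_cortical_trabecular()` fills each axial slice of the shell ring
  and labels bone within `shell_depth` voxels of the envelope boundary
  (2D distance transform, half-voxel centre-to-boundary correction) as
  cortical. Morphological closing is available to repair interrupted
  rings but is off by default because it dilates the discrete envelope
  outward by up to a voxel and shifts the rim.
* `warp_volume()` uses inverse mapping (sample at $x - u(x)$): no holes,
  the standard construction in registration validation. The ground truth
  a registration of such a pair should recover is the fixed-frame field
  solving $d(x) = u(x + d(x))$, which the package computes by fixed-point
  iteration when scoring.

# Design choices on genuinely open points

* **Experimental on x, predicted on y** in all regressions; RMSE is
  measured against the 1:1 line (prediction error), not the fitted line,
  and RMSE% divides by the absolute maximum experimental value.
* **Back-calculation** uses the origin-constrained closed form
  $s = \sum AF_{pred} AF_{exp} / \sum AF_{pred}^2$ rather than re-solving
  at trial moduli: linearity in $E_t$ makes re-solving redundant, and the
  scale applied to the packaged reference forces reproduces the reference
  4.6 GPa after rounding to one decimal.
* **Percentage force differences** are reported integer-rounded alongside
  the raw value, matching the convention of the reference table.
* **End-to-end recovery** (`run_parameter_recovery()`) generates the
  synthetic "experimental" forces by solving the same segmented mesh at a
  known true modulus under affine axial-compression end-plane conditions,
  then runs the validation leg with the boundary values sampled exactly
  through the DVC-grid interface (trilinear interpolation reproduces
  affine fields exactly, so the loop closes to solver precision). The
  validation solve is performed independently even when the reference
  modulus equals the true one.
* **Boundary layer** means exactly one node plane at each axial extreme.

# Known limitations

Linear elasticity cannot represent post-yield behaviour: specimens with
many elements beyond the compressive yield limit will show systematic
displacement overestimation no matter how the modulus is tuned, which is
precisely what the yield-fraction report is for. The DVC solver is global
(one smooth field); it will underestimate displacement discontinuities
such as cracks. Strain output on the DVC grid is far coarser than the FE
strain field and is only suitable for qualitative comparison. The
back-calculated modulus compensates for segmentation, partial-volume and
modelling errors as much as for tissue properties, and is therefore
specific to the imaging and modelling pipeline that produced it.
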