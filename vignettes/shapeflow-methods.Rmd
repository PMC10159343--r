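---
title: "Shape-driven surrogate haemodynamics: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-driven surrogate haemodynamics: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patient-specific computational fluid dynamics (CFD) of the aorta can
estimate pressure and velocity fields non-invasively, but a conventional
solver run takes minutes and an engineer to set up. `shapeflow` implements a
surrogate pipeline: a statistical shape model (SSM) of the thoracic aorta
parameterises anatomy with a few dozen PCA coefficients, a large synthetic
cohort is sampled from that shape space, a ground-truth solver labels every
synthetic subject with full 3D pressure and velocity-magnitude fields, and a
small dense neural network learns the map from shape coefficients to
PCA-reduced field coefficients. At inference time a new shape is registered
to the template, projected to its shape scores, and the network plus a
frozen inverse-PCA layer reconstructs full per-node fields in milliseconds.

Everything is exercised end to end at desk scale on synthetic anatomy: the
package generates its own cohorts, so no imaging data is required.

## The shape model

**Template and deformations.** Anatomy is modelled as deformations of a
template: a set of `n_cp` control points \(q_i\) carries momenta vectors
\(\mu_i\), and ambient points move along the kernel-weighted velocity field
\(v(x) = \sum_i K(x, q_i)\,\mu_i\) with a Gaussian kernel
\(K(x,q) = \exp(-\lVert x-q\rVert^2/\sigma^2)\), kernel width
\(\sigma = 10\) mm by default. The flow is integrated with `n_steps` Euler
steps (default 10); control points are advected by the same field while
their momenta are held fixed. This is a deliberate simplification of full
geodesic (Hamiltonian) shooting: it preserves the smooth, kernel-controlled
diffeomorphic character the pipeline needs, while keeping every Jacobian
auditable. Full geodesic shooting is an extension point, not a goal.

**Registration.** A target surface is first rigidly aligned by iterative
closest point (Kabsch least squares on nearest-neighbour correspondences),
then momenta are estimated by minimising the symmetric mean squared
nearest-neighbour vertex distance plus the kernel norm
\(\lambda \sum_{ij} K(q_i,q_j)\, \mu_i \cdot \mu_j\).

The optimiser deserves a note. Plain gradient descent with an adaptive step
stalls 0.2–0.3 mm short on self-consistency benchmarks: nearest-neighbour
correspondences lock onto wrong partners around the coarctation waist and
create local minima, a well-known failure of ICP-style objectives.
`fit_momenta()` therefore runs three phases, all built on a damped
Gauss–Newton (Levenberg–Marquardt) step that uses the kernel weights
accumulated along the current flow trajectory as a frozen Jacobian
(\(x_{\text{final}} \approx x_0 + W\mu\)):

1. *soft-correspondence annealing* (EM-ICP style): hard nearest neighbours
   are replaced by Gaussian-weighted soft targets over the 10 nearest
   vertices; the temperature starts at twice the median closest-point
   distance and cools geometrically (factor 0.85 to 0.2 mm);
2. *graduated regularisation*: the kernel-norm weight steps down decade by
   decade to the requested \(\lambda\);
3. *exact nearest-neighbour refinement* at \(\lambda\), whose accepted loss
   sequence is non-increasing by construction (damping is raised until a
   step decreases the loss) — this is the phase reported in `loss_trace`.

On known-momenta recovery benchmarks this reaches 0.002–0.06 mm mean
surface distance across seeds; the regularisation default is
\(\lambda = 10^{-3}\), and recovery experiments use \(10^{-5}\) where bias
matters more than smoothness.

**Control-point truncation.** The model is initialised with a ~500-point
lattice over the padded template bounding box, pruned to points within
\(\sigma\) of the surface, and after fitting a population is truncated to
the control points with the highest total momenta variance (default 172,
giving the 516-coefficient deformation vectors used downstream).

## Shape and field PCA

One PCA implementation serves both spaces: columns are standardised (mean
removed, unit variance; constant columns flagged and excluded from the
modes), the standardised matrix is decomposed by SVD, and modes are kept
either to a cumulative variance target — 0.99 for shape and pressure — or as
a fixed count — 55 for velocity, where variance is spread over many modes
and chasing 99% has strongly diminishing returns. Synthetic cohorts are
drawn mode-wise from Gaussians fitted to the training scores,
rejection-resampled to stay within ±2 SD. Rejection rather than clipping:
clipping would pile probability mass onto the truncation boundary, which the
sampled-within-two-SD reading does not support. Mode means are estimated
from the training scores, not assumed zero.

## The pseudo-CFD ground truth

The commercial steady laminar Navier–Stokes stage is **not** reproduced.
In its place stands a declared, deterministic Poiseuille-based closure:

* volumetric flow \(Q = v_{\text{in}} \pi r(0)^2\) with the uniform inlet
  velocity 1.3 m/s, conserved along the vessel;
* per cross-section, mean axial velocity \(\bar v(s) = Q / (\pi r(s)^2)\)
  and a parabolic profile
  \(v(d) = 2\bar v(s)\max(0, 1 - (d/r)^2)\) over distance \(d\) from the
  centerline;
* pressure integrated upstream from the 0 Pa outlet with
  \(\mathrm{d}P/\mathrm{d}s = 8\mu Q / (\pi r(s)^4)\), constant across each
  cross-section; blood density 1060 kg/m³ and viscosity 0.004 Pa·s.

Geometry is millimetres everywhere; the solver converts to SI internally.
The closure was chosen because (a) fields depend smoothly but nonlinearly
(\(r^{-4}\)) on shape, so the learning problem is real, and (b) closed forms
exist, so the solver can be held to analytic oracles (a straight 10 mm ×
250 mm tube must drop exactly 104 Pa). What a green surrogate test does
*not* establish: anything about recirculation, secondary flow, turbulence or
pressure recovery — none of which exist in this closure.

The paper-scale million-voxel Voronoi resampling grid is replaced by direct
nearest-neighbour assignment (the Voronoi kernel's limit); targets whose
nearest source exceeds the 5 mm padding are counted and reported, not
dropped. The interpolation stage can be emulated with a jittered evaluation
cloud (`jitter_resample`), and its cost is reported as the cohort-mean
percentage error of 99-station centerline gradient curves.

## The surrogate networks

Independent dense networks for pressure and velocity map shape scores to
field scores: ReLU hidden layers, linear output, and a frozen inverse-PCA
reconstruction appended so the mean-absolute-error loss is computed on the
full per-node field. Computing the loss after reconstruction weights every
mode by the variance it explains, which score-space MAE would not.
Optimisation is Adam with batch size 32; tuning uses 50 epochs and 5-fold
cross-validation with floor-balanced folds (the source protocol's stated
fold size is internally inconsistent with its training-set size, so balance
is the only defensible reading). The field basis is refit on training rows
only inside each fold. Hyperparameter search (layers 1–4, width 16–256
log-spaced, learning rate \(10^{-4}\)–\(10^{-2}\) log-uniform) is random by
default, with a light tree-structured Parzen estimator as an option;
pruning is out of scope and a fixed trial budget stands in for it.

## Evaluation metrics

* **NAE** per node: \(|{\rm true} - {\rm pred}|\) divided by the subject's
  ground-truth field range, ×100. MNAE_N averages over the population per
  node, MNAE_S over nodes per subject; the population error is the mean ±
  SD of MNAE_S.
* **Bland–Altman**: bias is the mean signed normalised error; limits of
  agreement are bias ± 1.96 SD.
* **Gradient curves**: 99 equally spaced arc-length stations from the root
  (flow extension excluded) to the outlet; each station averages the field
  over the nodes whose nearest-centerline arc length falls in its slab.
  Empty slabs (possible on coarse fixtures) inherit the nearest non-empty
  value and are counted in a warning.
* **Discrete Fréchet distance** via the standard dynamic program, computed
  on the 1D value sequences at shared stations so the result keeps the
  field's units (Pa, m/s). Whether the source metric also couples the
  arc-length coordinate is not stated; a 2D variant is available behind
  `use_positions = TRUE` without any parity claim.
* **Centerline geometry**: length, mean diameter, tortuosity (arc length
  over endpoint chord) and mean torsion from a centred finite-difference
  Frenet estimator with arc-length weights (zero wherever the local
  osculating plane is degenerate, so straight and planar curves report
  exactly zero). Cohorts are compared with Welch's t-test.

## The synthetic world

The generator stands in for a segmented patient population with a
candy-cane geometry: a circular arch (radius 35 ± 3 mm, angle 180 ± 10°)
joined to a straight descending segment (150 ± 12 mm), lumen radius
10 ± 1 mm (mean diameter ≈ 20 mm, matching the cohort the pipeline
emulates), 30% linear taper, and a Gaussian mid-descending narrowing
(severity 0.25 ± 0.12 of local radius, half-width 12 mm) emulating residual
coarctation. Targets are generated **analytically** from perturbed
generating curves — not by deforming the template — so registration is
tested against shapes it cannot represent exactly. Clip planes are not
reproducible from the source cohort, so the generator defines its own
endpoints; inlet/outlet rings are tagged at generation time rather than
detected heuristically. Default resolutions are ~2,500 surface vertices and
~9,500 volume nodes (configurable), desk-scaled from the source's
2,541/29,000.

What the generator does *not* emulate: branch vessels, non-circular lumen
cross-sections, segmentation noise, or out-of-plane arch torsion (the
generating curve is planar, so cohort torsion statistics centre on zero).

## Numerical choices and degenerate inputs

* Zero-variance PCA columns get SD 1 and are flagged; they reconstruct to
  their mean exactly.
* A zero-range ground-truth field makes NAE undefined and is rejected
  explicitly rather than returning infinities.
* Pearson correlations against a zero-variance mode are reported missing,
  not zero.
* Both-samples-constant Welch comparisons return p = 1 when means agree,
  p = 0 otherwise.
* The pseudo-CFD solver rejects meshes whose nodes sit farther than 1.5 ×
  the local radius from the centerline (mesh/centerline mismatch).
* After shooting, a subject's centerline is re-centred on the wall-node
  centroid of each axial station and its effective lumen radius
  re-estimated as the RMS wall distance — equal to the true radius for
  circular sections and robust when a deformed ring cuts the lumen
  obliquely; the centerline is then arc-length-refined to ≤ 2.5 mm spacing
  so nearest-station assignment cannot jump across strong radius
  gradients.
* Rare extreme synthetic subjects (tail ±2 SD score combinations, e.g.
  self-approaching sharply angulated arches) violate the solver's validity
  bound; the cohort sampler rejects and replaces them from a 2n
  oversampled pool, warning with the count. The cohort is therefore, by
  construction, a cohort of solvable anatomies; the validity threshold is
  never relaxed.
* Stage seeds derive from the global seed by a 31-bit rolling hash of the
  stage name (`derive_seed()`), so any stage can be reproduced in
  isolation and no seed exceeds `2^31 - 1`.

## Desk-scale defaults and budgets

Pipeline defaults are desk-scaled versions of the source protocol: 40
registration targets (vs 67), 350 synthetic subjects (vs 3,000), ~9,500
correspondence nodes (vs 29,000), final training 200 epochs (vs 1,000) —
each overridable to paper scale through `run_config()`. The acceptance
experiment in the test suite runs the full chain at further reduced mesh
resolution (~700 surface vertices, ~1,800 volume nodes) to stay within a
ten-minute single-CPU budget; the error thresholds it must meet are not
scaled.

## Known limitations

* The Poiseuille closure is the central honest deviation from a
  Navier–Stokes ground truth; surrogate accuracy here bounds nothing about
  surrogate accuracy on real CFD data.
* The simplified kernel flow is not a geodesic; momenta are comparable
  across subjects only because all fits share the template, kernel and
  step count.
* Fréchet distances are reported in field units on value sequences; they
  are not comparable to implementations that couple spatial coordinates.
* The registration loss is vertex-based (no currents/varifolds), adequate
  for fixture surfaces of comparable sampling density, fragile under very
  different mesh densities.
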