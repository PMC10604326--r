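---
title: "Methods: shape modelling and measurement-conditioned prediction of the proximal humerus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape modelling and measurement-conditioned prediction of the proximal humerus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(humerusSSM)
```

This vignette is the package's own account of its methods: the
point-distribution shape model, the measurement-conditioning mechanism,
the alignment and correspondence machinery, the synthetic-anatomy
generator that provides ground truth, and the numerical and design choices
made where more than one convention was defensible. Everything quantitative
stated here is computed by the package's test suite or by
`scripts/acceptance.R`; this document states no empirical result beyond
what those runs produce.

## 1. The point-distribution model

The carrier of anatomy is the triangle surface mesh in millimetres
(`surface_mesh`), typically segmented from CT and exported as STL. A
cohort of M bones is brought into *dense correspondence* — vertex i means
the same anatomical locus on every bone — and each corresponded shape is
flattened to a 3N-coordinate vector. After pose removal the model is plain
PCA:

$$ S = \mu + \sum_{i=1}^{K} w_i\, \mathrm{sd}_i\, m_i, \qquad S \sim
\mathcal{N}(\mu, \Sigma), $$

with the arithmetic mean \(\mu\), orthonormal modes of variation \(m_i\),
and per-mode standard deviations \(\mathrm{sd}_i\) in mm. Weights are
stored in sd units; the familiar "±3 SD" mode visualizations are
`synthesize(model, c(3, 0, ...))`.

Numerical conventions, chosen once:

* **Covariance divisor M−1** (sample covariance). For compactness
  percentages the divisor cancels, so the choice is a documentation
  convention rather than a substantive one.
* **Gram-matrix eigendecomposition.** With 3N in the tens of thousands and
  M ≈ 100, the M×M Gram matrix gives the identical nonzero spectrum at a
  fraction of the cost; the tests verify equality with the direct
  covariance eigendecomposition to 1e−8 on small instances.
* **Rank truncation** at a relative eigenvalue threshold of 1e−12: modes
  that carry only numerical noise are discarded. A consequence worth
  knowing: the PCA reconstruction identity `synthesize(project(x)) = x`
  is exact only when the training variation truly lies in the retained
  span; populations with mildly nonlinear latent effects retain a
  sub-micrometre residual.
* **Mode sign convention**: the entry of largest magnitude in each mode is
  made positive. Eigenvector signs are otherwise arbitrary and would make
  runs irreproducible.
* **No probabilistic noise floor** (no PPCA): the model is plain PCA.

Compactness — the cumulative eigenvalue fraction — is the model-quality
diagnostic (`compactness()`, `modes_for_variance()`, and the `plot()`
method). On real cohorts of around 140 adult humeri, a handful of modes
(reported as eight in the clinical literature this package accompanies)
explain 95% of the variance; on the synthetic populations below the count
is governed exactly by the number of active latent factors, which is what
the rank-recovery tests exploit.

## 2. Alignment without scaling

Pose differences are nuisance variation; size is anatomy. All alignment
therefore uses rotations and translations only.

* `icp_rigid()` — iterative closest point with point-to-*surface* matching
  (closest point on triangle, not nearest vertex, which is materially more
  accurate at 1.5 mm edge length) and the Kabsch/SVD solution with the
  determinant forced to +1, so a mirrored input can never be absorbed into
  a reflection. Manual pre-alignment is replaced by a centroid +
  principal-axes initialization with the four proper-rotation sign
  disambiguations scored by matched distance.
* `align_set()` — generalized Procrustes: iteratively align every shape to
  the running mean, recompute the mean, stop when it moves less than
  1e−6 mm. The output frame is canonicalized from the mean's own principal
  axes (signs fixed by third moments), so the result is invariant to the
  poses the shapes arrived in — Procrustes alone is only defined up to one
  global rotation.
* Nearest-point ties are broken by the lowest triangle index, which makes
  every downstream computation deterministic.

## 3. Dense correspondence by template warping

`warp_template()` deforms a template mesh onto a target surface while
preserving the template topology. The deformation is a per-vertex
displacement field fitted by non-rigid ICP: each template vertex is
matched to its closest target point and the field minimizes

$$ \sum_i \lVert x_i + d_i - c_i \rVert^2 \;+\; \lambda \sum_{(i,j) \in
\text{edges}} \lVert d_i - d_j \rVert^2 $$

— a sparse symmetric positive-definite solve (graph Laplacian on template
edges, solved with `Matrix` Cholesky factorizations reused across inner
iterations). The stiffness schedule is coarse-to-fine, default
λ ∈ {1000, 100, 10, 1} with 10 matching iterations per level.
Initialization is rigid ICP followed by a short *global affine* ICP stage:
bones differ most in length and girth, and absorbing that stretch globally
prevents the tangential correspondence drift that a pure
displacement-field warp otherwise accumulates along the shaft.

Two different accuracies must be kept apart:

* **Surface fit** (how close the warped template lies to the target
  surface): 99th-percentile distances far below 0.1 mm at 1.5–3 mm
  resolution in the tests.
* **Correspondence accuracy** (whether warped vertex i lands at the
  anatomically correct spot): testable only on synthetic pairs with known
  ground truth. For latent differences of about half a population SD the
  99th-percentile correspondence error stays below 1 mm; it grows roughly
  linearly with the shape difference, and is fundamentally limited on
  rotationally symmetric regions — a tangential slide on the spherical
  head cap is invisible to closest-point matching. In the evaluation
  pipeline the warp is applied to pairs that are already very similar
  (prediction vs. original, left vs. mirrored right), well inside this
  regime.

This warp is a stand-in for whatever proprietary warping a commercial
pipeline would use; it is validated only against the synthetic ground
truth and claims no equivalence to any specific product.

## 4. The measurement-augmented model and conditioning

Three parameters remain measurable on many fractured humeri: maximum
length, head radius, shaft circumference. `shape_model(shapes,
measurements = ...)` appends them to each training vector and recomputes
the PCA, making the measurements part of the model; the seven non-empty
subsets of the three parameters are compared by
`evaluate_combinations()`.

**Measurement scaling.** The appended block must carry *some* variance
(or it cannot steer the model) but not distort the shape modes. Each
measurement is standardized to unit training SD and multiplied by one
balance factor chosen so the whole block carries 1% of total augmented
variance (`measurement_weight = 0.01`). Because prediction constrains the
block *exactly*, the predicted shape is insensitive to this factor — the
tests sweep it over two orders of magnitude and require identical
predictions to 1e−6 mm. The knob exists, but nothing of scientific
substance hangs on it.

**Conditioning.** `predict()` on an augmented model solves for the
minimum-Mahalanobis-norm weights subject to the measurement rows matching
the scaled targets,

$$ w = B^\top (B B^\top + \varepsilon I)^{-1} t, $$

with \(B\) the measurement rows of the sd-scaled mode matrix and ridge
\(\varepsilon = 10^{-8}\) guarding against near-collinear measurements
(length and radius correlate in realistic cohorts). Whenever the
measurement sub-covariance is nonsingular this *is* the Schur-complement
conditional mean of the joint Gaussian; the tests verify agreement with
that closed form to 1e−6 mm on small instances. A hard constraint was
chosen over a soft (regularized-regression) one because it is the
canonical semantics of "set a target value for the measurements" and is
testable against the closed form. Targets more than 5 training SDs from
the training mean set an `out_of_range` flag rather than erroring —
fracture cases may legitimately sit at population extremes.

## 5. Anatomical measurements

The humeral coordinate system (`build_hcs()`) is anchored at the centre of
a sphere fitted to the articular surface (Kåsa linear least squares plus
one Gauss–Newton refinement pass); the y-axis runs from the distal
epicondyle midpoint through that origin, pointing proximally; the x-axis
is the normal of the plane through the origin and the two caudal
epicondyle points, oriented medial→lateral; z completes the right-handed
triad.

* **Maximum length**: distance between the two extreme supporting planes
  normal to y. Extremes are taken over vertices, not interpolated surface
  points; at 1.5 mm resolution the difference is below measurement
  tolerance. Note that the most distal *vertex* need not be the trochlea
  landmark itself; the supporting-plane definition is the one implemented.
* **Head radius**: radius of the articular sphere fit.
* **Shaft circumference**: the bone is cut by the plane normal to y
  through the deltoid-tuberosity landmark (the operational stand-in for
  "halfway along the diaphysis", which coincides with the most protruding
  tuberosity point by construction of the generator and by assertion in
  the clinical protocol); the measured value is the perimeter of the
  closed cross-section contour that encloses the shaft axis, so a bump or
  a second contour (e.g. through the head) cannot corrupt it. Vertices
  exactly on the cutting plane are nudged by 1e−9 mm so contour chaining
  never breaks; the perimeter error this introduces is of the same order.

Landmarks are template-defined and propagated through correspondence
rather than re-detected per mesh, which removes observer dependence.
Measurement reliability is quantified by the two-way mixed-effects,
absolute-agreement, single-measure ICC computed from two-way ANOVA mean
squares — the literature this package accompanies names only "ICC", and
this is the standard form for one observer repeating a measurement; the
tests pin the arithmetic to a brute-force `aov()` computation.

## 6. Proximal-segment evaluation

`extract_proximal_segment()` fits the diaphysis cylinder axis on the
mid-shaft band (30–70% of the long-axis extent; axis direction initialized
from covariance eigenvectors and refined by Nelder–Mead over the unit
sphere, with the in-plane circle centre solved in closed form), orients it
towards the wider (head) end, and cuts 60 mm from the most proximal point
— per bone, in that bone's own geometry, which is rigid-invariant. Cuts
split straddling triangles exactly and are left *uncapped*: a cap would
pollute the deviation statistics with artificial surface.

`deviation_map()` evaluates every vertex of segment A against surface B:
signed point-to-surface distance (positive = A outside B, by B's outward
normal at the closest point), area-weighted (each vertex carries one third
of its incident triangle areas — the bin percentages are fractions of
*surface area*, a choice the clinical sources leave unstated), binned at
1 mm and 2 mm by absolute value, with signed summaries kept separately so
systematic over-/underestimation remains visible. In `compare_prediction()`
the *candidate* (predicted) segment takes the A role, so a uniformly
fatter prediction yields a positive mean deviation — an overestimation.
`compare_contralateral()` mirrors the right bone and runs the identical
pipeline, which is the clinical gold-standard baseline.

Both full bones are first rigidly aligned (no scaling); both segments are
then warped from one common segment template (by default the canonical
generator template's proximal segment, built at a resolution that yields
approximately the requested 1952 vertices) so the two deviation arms use
the same evaluation vertex set.

## 7. The synthetic-anatomy generator

No CT data ship with this package, so validation rests on a parametric
humerus-like generator with exact ground truth. Seven latent factors drive
it: maximum length, head radius, shaft radius, neck-shaft angle, medial
head offset, deltoid-tuberosity prominence, epicondylar width. The
template is a structured ring grid: a circular shaft, a lateral deltoid
bump at mid-diaphysis, epicondylar widening and a trochlear taper
distally, and proximally a *exact spherical cap* for the articular
surface, blended into the shaft over a neck region and offset medially.
The neck-shaft angle both shifts the head centre and scales the cap
extent, so each factor has a geometrically independent effect. Landmarks
(articular vertex set, caudal epicondyle points, trochlea, head apex,
deltoid tuberosity) are identified constructively during generation.

Key properties, all under test:

* **Correspondence by construction**: `instantiate_humerus()` recomputes
  vertex positions for a new latent on the fixed template topology, so
  vertex i is the same locus in every instance; articular vertices lie on
  the generating sphere to machine precision; the generator records exact
  length, head centre/radius and section perimeter per instance as ground
  truth.
* **Near-affine latent action**: region boundaries and ring radii are
  affine in the latents wherever possible, so a population driven by k
  factors is captured by ≈k linear modes (the rank-recovery tests use
  k ∈ {1, 2, 3, 7}). The neck-shaft angle enters through a cosine and is
  the one mildly nonlinear factor.
* **Populations**: `sample_population()` draws latents independently per
  field from normal distributions truncated to the validity box (joint
  rejection). Default means (length 310 mm, head radius 24 mm, shaft
  radius 10 mm, neck-shaft angle 135°, head offset 6 mm, deltoid
  prominence 2 mm, epicondylar width 60 mm) and SDs (20 mm, 1.5 mm, 1 mm,
  4°, 1 mm, 0.4 mm, 3 mm) are generator conventions chosen from general
  adult anatomical ranges — realistic magnitudes, not fitted to any
  dataset.
* **Bilateral pairs**: the right bone is the mirrored instantiation of the
  left latent plus truncated-normal asymmetry noise. The default
  asymmetry SDs in `run_validation_experiment()` (length 2 mm, head radius
  0.4 mm, shaft radius 0.4 mm, head offset 0.4 mm, neck-shaft angle 1.5°)
  encode that healthy left–right differences are distinctly smaller than
  inter-individual variation.

**What passing tests do and do not show.** The generator's head is a
perfect sphere and its shape manifold is essentially linear in the
latents. Consequently two parameters (length + head radius) predict the
synthetic proximal segment almost completely, and in the synthetic
experiment the SSM arm can match or beat the contralateral arm once any
bilateral asymmetry is present. Real humeri are not like this: tuberosity
shape, retroversion and head inclination vary in ways largely uncorrelated
with the two parameters, which is why clinical data show the contralateral
method ahead (and why the degenerate-limit check — zero asymmetry, where
the contralateral arm is exact — is the qualitative anchor the synthetic
study can honestly reproduce). Passing here validates the *machinery* —
correspondence, conditioning, deviation mapping — not the clinical effect
sizes.

## 8. Problem sizes and determinism

The synthetic studies run at template mean edge lengths of 4–5 mm
(roughly 1 200–1 800 vertices per bone; the clinical convention of 1.5 mm,
about 13 000 vertices, is exercised where the oracle demands it, e.g. the
deviation-map offset test), with training cohorts of 25–100 shapes and 8
validation pairs, and 800–1952-vertex segment templates. These sizes were
chosen so the full statistical behaviour is exercised at desk scale; every
stochastic step draws from an explicit seed, and the tests assert bitwise
reproducibility for the generator, the CLI `simulate` command and the
conditional prediction.

## 9. Known limitations

* The generator is humerus-*like*, not anatomically exact: no retroversion
  torsion of the distal relative to the proximal bone, no cortical
  thickness or interior structure, no pathological or fractured shapes.
* Correspondence accuracy of the warp degrades on rotationally symmetric
  surfaces and for large shape differences (Section 3).
* Binary STL stores 32-bit floats; round-trips through STL are exact only
  to single precision (about 2×10⁻⁵ mm at a 300 mm coordinate). PLY and
  OBJ are written with 12 significant digits.
* The model is linear-Gaussian throughout; no kernel or nonlinear shape
  models, no posterior uncertainty on predictions, and no prediction from
  partial surface geometry (distal-segment fitting) — the last is the
  natural next step for fracture cases where length cannot be measured.
* Generalization and specificity metrics beyond compactness are not
  implemented; descriptive deviation statistics, not hypothesis tests,
  compare the two reconstruction arms.
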