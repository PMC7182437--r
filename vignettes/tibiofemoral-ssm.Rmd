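---
title: "A tibio-femoral statistical shape model and knee-instability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A tibio-femoral statistical shape model and knee-instability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(kneessm)
```

## The problem

Tibio-femoral alignment — the three-dimensional rotation of the femur
relative to the tibia — is summarised clinically by five angles: the
hip-knee-ankle angle (HKA), femoral and tibial varus-valgus (FVV, TVV),
internal-external femoral rotation (IER), and tibial slope (TS). Each has
a physiological range (HKA 0±3°, FVV −6±2°, IER 0±5°, TVV 0±5°, TS 7±4°);
a knee outside a range is considered mechanically unstable for that angle.
Measuring the angles requires bony landmarks (hip centre, epicondyles,
plateau points, ankle centre) that are tedious to identify and unreliable
on severely deformed, osteoarthritic bones.

This package implements the landmark-free alternative: a joint statistical
shape model (SSM) of the distal femur and proximal tibia. Corresponding
surface points across a cohort are stacked into shape vectors; principal
component analysis yields a mean shape and orthogonal modes of variation
(MoVs). Projecting a new knee onto the model produces a handful of mode
weights, and classifiers trained on those weights predict per-angle
stability without any landmarks. The package covers the whole chain —
synthetic cohort generation, mesh preprocessing, rigid and deformable
registration, shape-space construction, angle computation, and the
statistical analysis relating mode weights to instability.

## The model

With $M$ corresponding shape vectors $s_k \in \mathbb{R}^{3P}$ (the $P$
reference-indexed points of femur and tibia, stacked), the model is

* mean shape $\bar m = \tfrac1M \sum_k s_k$;
* modes $v_i$ and mode standard deviations $\sigma_i$ from the
  eigendecomposition of the sample covariance of $s_k - \bar m$
  (computed through the $M \times M$ Gram matrix; at most $M-1$ modes);
* explained variance $EV_j = \sigma_j^2 / \sum_i \sigma_i^2$;
* morphing $\check S = \bar m + \sum_i \lambda_i \sigma_i v_i$, with
  weights $\lambda_i$ in SD units so $\lambda = 0$ is the mean shape;
* projection $\lambda_i = v_i \cdot (s - \bar m) / \sigma_i$.

Enough modes are retained to cover 95% cumulative explained variance
(configurable). Storing $\sigma_i$ as standard deviations is the single
convention that makes the morphing formula (which multiplies
$\lambda\sigma v$) and the explained-variance formula (which squares
$\sigma$) consistent. Mode signs are arbitrary in PCA; we fix each mode's
largest-magnitude component to be positive so results are reproducible.
The covariance divisor is $M-1$. There is no iterative mean/pose
re-estimation: a single rigid alignment pass precedes the PCA, and no size
normalisation is applied anywhere — scale and shaft-length differences are
deliberately kept in the model, because normalising a two-bone complex
would distort the relative size of femur and tibia, which is itself
informative.

## Correspondence construction

Every sample pair is rigidly registered (rotation + translation, never
scale) as a single concatenated femur+tibia cloud to a reference pair, so
the sample's internal femoro-tibial pose and joint space are preserved —
this is what lets alignment differences survive into the shape space.
Registration is iterative closest point with a Procrustes inner step,
initialised from landmark Procrustes when landmarks are available and from
centroid + principal axes otherwise.

Dense correspondence is then computed per bone: coherent point drift (CPD)
deforms the reference bone's vertices toward the sample with a smooth
Gaussian-kernel motion field estimated by EM on a Gaussian mixture with a
uniform outlier component, and each deformed vertex is projected onto its
closest point on the sample surface (projections beyond a 5 mm gate are
kept at the deformed position and flagged). The output always has the
reference's vertex count and order. Whether to project onto the surface or
snap to nearest sample vertices is a genuine design choice; projection was
chosen because it is insensitive to the sample's tessellation.

The reference is chosen deterministically as the cohort sample whose five
angles deviate least, in summed absolute value, from the physiological
centres — a reproducible analogue of picking a low-deformity reference at
random — and is remeshed to a uniform edge length before use.

### CPD parameters

Point sets are centred and scaled to unit RMS radius inside the
registration, so the kernel width `beta` and regularisation `lam` are in
normalised units. The defaults are `beta = 3`, `lam = 10`, stiffer than
the textbook `beta = 2`, `lam = 3`. The reason is measurable: as the
mixture variance anneals below the target's vertex spacing, a compliant
field locks each moved point onto the nearest target vertex, so
correspondences inherit the sample's arbitrary tessellation. On cohorts of
identical geometry differing only by 0.2 mm vertex noise (where ideal
correspondences would be identical), the stiffer field reduces the
per-coordinate correspondence spread from ≈0.76 mm to ≈0.22 mm while
*also* fitting true deformations better (mean residual 0.066 mm vs
0.19 mm on a strongly deformed sample; a smooth 5° bend is recovered to
below 1e-3 mm) and converging in a small fraction of the EM iterations.
Both parameters remain configurable. The motion field is parameterised in
a truncated eigenbasis of the Gaussian kernel (rank 60 by default),
scaled so the smoothness prior becomes a plain ridge; at these kernel
widths the spectrum decays so fast that the truncation is numerically
irrelevant, and it turns the $O(M^3)$ M-step solve into a
well-conditioned $K \times K$ system. The penalised log-likelihood trace
is monotone non-decreasing (a generalised-EM property) and is checked in
the tests.

## Mesh processing

* **Smoothing** is Taubin's λ/μ scheme (λ = 0.5, μ = −0.53), chosen over
  plain Laplacian smoothing because it attenuates noise without shrinking
  the surface (volume drift < 1% over 10 iterations on a sphere).
* **Decimation** is quadric edge collapse with link-condition and
  normal-flip guards; non-manifold input is an explicit error rather than
  silently repaired.
* **Remeshing** of the reference is incremental isotropic remeshing
  (split / collapse / flip / tangential relaxation with back-projection
  onto the input surface).
* **Surface distances** are vertex-sampled, point-to-triangle, symmetric
  (Hausdorff = max of both directed maxima) — vertex-to-vertex distances
  would be biased by tessellation differences after decimation.
* The package-wide coordinate convention is x = medio-lateral (+lateral
  on a right knee), y = antero-posterior (+anterior), z = proximo-distal
  (+proximal); left bones are mirrored by negating x (with a winding flip
  to keep normals outward).

## Clinical angles

All five angles are measured by projecting axes into the frontal (x, z),
sagittal (y, z) or axial (x, y) plane, as in radiographic practice, after
re-deriving a canonical anatomical frame from the landmarks themselves
(z along the tibial mechanical axis, x along the tibial plateau ML line
orthogonalised against it). The re-derived frame makes the measurement
exactly invariant to global rigid motion. Sign conventions — varus
positive, valgus negative, posterior slope positive, external rotation
positive — are fixed so the physiological values land where clinicians
put them (FVV centre −6°, TS centre +7°). With parallel joint lines the
identity FVV + TVV = HKA holds exactly. Stability labels use closed
intervals (a boundary value is stable), since the ranges are quoted as
ranges, not strict inequalities. For correlation analyses each angle is
also available as a corrected deviation $\hat X = |X - \bar X|$ from its
physiological centre, since both directions of departure mean instability.
The exact landmark recipe per angle (e.g. the epicondylar rather than the
posterior-condylar axis for IER) is one consistent reading of standard
practice and is kept in one place (`compute_angles`) so it can be swapped.

## The synthetic cohort generator

Real CT-derived cohorts are not redistributable, so the package ships a
parametric generator that emulates their structure: per bone a bent
elliptic-cylinder shaft with configurable length (femur 20–40 mm, tibia
20–30 mm past the joint block, mimicking variable scan crops), two
condylar lobes with an intercondylar notch on the femur, a flattened
elliptic plateau on the tibia, left/right sides by mirroring, and known
ground-truth angles. Deformations are applied in a fixed order — scale,
shaft elongation/diameter, frontal bow, condyle/plateau sizing, joint-line
tilts, pose rotations, mirroring, vertex noise last — so landmark
transport is well defined; landmarks stay noise-free so the recorded
angles are exact. The shaft bow vanishes at both shaft ends, leaving the
mechanical-axis endpoints untouched.

Because plane-projected angle measurements interact under combined
rotations (an axial rotation seen through a frontal rotation projects to
a slightly different axial angle), the generator solves the five tilt and
pose rotations by fixed-point iteration until the *measured* angles equal
the requested ones to below 1e-8°; the iteration converges in a handful of
steps since the cross-talk is second order. Regional rotations (joint-line
tilts) are blended along the shaft with a smoothstep weight that is
exactly 1 at every joint landmark and exactly 0 at the axis proxies, so
the closure is exact, and the mesh deformation stays smooth.

Default cohort distributions are truncated normals (±3 SD, avoiding
self-intersecting geometry). The angle SDs (HKA 8°, FVV 6°, IER 3.5°,
TVV 3.9°, TS 3.8°) were chosen once so that the per-angle unstable
fractions roughly reproduce the class imbalance of a surgical
osteoarthritis population (about 70–75% unstable for the frontal-plane
angles, 15–30% for the others); they are config-exposed.

The template is built from smooth primitives, not from a scanned bone:
every acceptance property here rests on statistical and geometric
structure (known latents, exact landmarks, controlled noise), not on
anatomical realism. Consequently, passing tests demonstrate that the
pipeline recovers what it is supposed to recover under its own generative
assumptions — smooth single-object surfaces, isotropic noise, exact
labels; they do not demonstrate robustness to segmentation artefacts,
osteophytes, cartilage, or manual-landmarking error, none of which the
generator simulates.

## The statistical layer

Per clinical angle, the positive class is "unstable" throughout.

* **LDA/QDA** are Gaussian discriminants written in-package because the
  analysis needs covariance shrinkage
  $\Sigma \leftarrow (1-\rho)\Sigma + \rho\,\mathrm{diag}(\Sigma)$
  (default ρ = 0.1): with ~30 features and classes as small as a dozen
  samples, raw QDA covariances are singular. At ρ = 0 the implementation
  is verified against the reference implementation in the tests.
* **Logistic regression** uses the standard IRLS fit with Wald z tests;
  complete separation or collinearity triggers a ridge-penalised IRLS
  fallback (penalty 1e-4, flagged in the output).
* **Leave-one-out validation** refits the classifier $n$ times; folds
  whose training set loses a class (or cannot estimate a class
  covariance) are flagged and excluded from the confusion counts. The
  shape model itself is built once on the full cohort and only the
  classifier is cross-validated — a deliberate mirroring of the original
  analysis design; the resulting leakage caveat is that the reported
  accuracies validate the classifier given the shape space, not the whole
  pipeline.
* **Low-dimensional subsets** are found by greedy forward selection on
  LOO accuracy with ties broken toward the lower mode index (verified
  exhaustively at small sizes in the tests). Greedy selection is a
  deterministic, testable choice; it is not claimed to be how any
  particular published subset was derived.
* **Group comparisons** use the unpaired two-sided Wilcoxon rank-sum
  test — exact enumeration of all rank splits for pooled n ≤ 12,
  tie-corrected continuity-corrected normal approximation otherwise. The
  stable/unstable groups are unpaired, which is why the unpaired test is
  the correct one here.
* **Correlations** are Spearman coefficients with average ranks for ties
  and a two-sided t-approximation p-value.
* No multiple-testing correction is applied by default (per-test
  p < 0.05), matching common practice in this literature; a
  Benjamini-Hochberg option exists and is off by default.

## Problem sizes, tolerances, degenerate inputs

The desk-scale profile used by the analysis scripts, the validation suite
and `scripts/acceptance.R` is a cohort of 20 with ~1,000 vertices per
bone — chosen as the smallest size at which all five latent parameters are
cleanly recoverable; population-scale settings (99 samples, ~6,000
reference nodes at 1.5 mm edges) are reachable through the same
configuration fields. Numerical choices worth knowing:

* Gram-trick eigenvalues below `1e-10` of the largest are treated as zero
  modes; projection onto a zero-variance mode returns weight 0.
* Rank-deficient cohorts (even all-identical shapes) produce a zero-mode
  model and a skipped analysis with a message, not an error.
* CPD aborts with a diagnostic if the mixture variance collapses to a
  non-finite value; a variance below 1e-10 (normalised units) is treated
  as converged.
* Reconstruction-error monotonicity in the retained mode count is
  guaranteed (and asserted) for the RMS point error, the quantity that
  nested orthogonal projections control; the mean and maximum point
  distances are reported alongside but are not individually monotone.
* The truncated-normal sampler is simple rejection; identical seeds give
  byte-identical cohorts.

## The calibrated benchmark cohort

`generate_benchmark_cohort()` defines the end-to-end validation
conditions: n = 20, exactly five latent parameters varying (the five
alignment rotations/tilts), 0.2 mm vertex noise, alternating sides. The
frontal rotation is drawn half near 0° and half near ±6°, i.e. class
centres separated by twice the 3° physiological HKA half-width, giving a
strong, known instability signal. The four nuisance angles use their
physiological SDs (IER 3.5°, TS 3.8°, FVV 2°, TVV 2°) rather than the
cohort-imbalance SDs: the femoral joint-line tilt displaces the condylar
region in the frontal plane, a field that overlaps the HKA femur
rotation's field, and at SD 6° it dominates the PCA and aliases the HKA
mode. With physiological nuisance variability the pipeline recovers the
frontal-rotation latent in a single dominant mode (|Spearman| ≳ 0.9),
reaches 95% cumulative EV within 8 modes, and classifies the HKA label
with LOO QDA accuracy ≥ 0.9 — the quantities `scripts/acceptance.R`
recomputes and reports.

## Known limitations

* The one-to-one correspondence step is CPD + closest-point projection;
  published robust matching refinements are not reproduced here.
* Groupwise (simultaneous) registration, affine CPD, kernel/nonlinear
  shape models and per-bone separate SSMs are out of scope.
* The statistical layer reports associations, not causal or anatomical
  interpretations of modes; interpreting what a mode "means" requires
  visual inspection that this package supports only indirectly (morphing
  surfaces to PLY for external viewers).
* Classification metrics on 20 synthetic samples have wide confidence
  intervals; the benchmark checks recovery of a designed signal, not
  clinical performance.
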