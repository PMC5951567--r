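---
title: "Methods: radiomic nodule characterization and validated classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic nodule characterization and validated classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(NoduleRadiomics)
```

# Scope and model

The package turns a segmented pulmonary nodule on CT into a 57-feature
quantitative description and fits an internally validated benign/malignant
classifier on cohorts of such descriptions. The statistical model is a
logistic regression on a sparse feature subset chosen by stability selection;
its headline performance number is the optimism-corrected AUC, i.e. the
apparent AUC minus a bootstrap estimate of how much the *entire* modeling
procedure flatters itself on its own training data.

The pipeline assumes: a single nodule per scan, fully contained in the volume
with surrounding lung present; Hounsfield-calibrated voxels (values are
clamped into [-1024, 3071]); and an approximately star-shaped lesion, so that
a closed genus-0 surface is a faithful boundary model. Coordinates are
world-mm: voxel (i, j, k), 0-based, sits at `origin + c(i,j,k) * spacing`.

# Segmentation

`regionGrowSegment()` is deliberately simple: a 6-connected flood over an HU
window inside an operator bounding cube. Texture-based parametric growing
used interactively on clinical data is replaced by the window rule, which is
sufficient for phantoms and keeps the same operator contract (cube + seed).
6-connectivity is conservative against diagonal leakage into vessels. If the
grown region reaches three or more cube faces the window has failed to
separate nodule from background and the call errors instead of returning a
runaway mask. `cleanMask()` keeps the largest component and fills internal
cavities (background components not touching the grid border); it is
idempotent. `surroundShell()` takes the exact anisotropic Euclidean distance
transform (computed in mm on the voxel-centre lattice) and keeps the
(0, d] band, 10 mm by default, optionally intersected with a lung mask.

A discretization note: with the centre-to-centre distance definition, the
digitized shell around a 10 mm sphere at 1 mm spacing is ~4% smaller than the
continuum annulus; at 0.5 mm it is within 2%. The definition is kept because
it is exact on the lattice (it is validated against an exhaustive
nearest-voxel search in the tests); users comparing shell volumes against
continuum values should do so at sub-millimetre spacing.

# Surface extraction and curvature

`extractMesh()` triangulates the 0.5 level set of the Gaussian-smoothed binary
mask by marching tetrahedra (six tetrahedra per cube). Every tetrahedral case
is unambiguous, so the surface is watertight and consistently oriented
(outward; enclosed volume positive), which the Euler-characteristic and
Gauss–Bonnet checks in the test suite rely on. Numerical choices:

* `gaussianSigmaMm` (default 1 mm): bandwidth of the pre-smoothing. Smoothing
  a binary indicator drags the 0.5 level set of a convex body inward by
  approximately sigma^2 * H. Rather than sharpening the field (which
  re-amplifies voxel noise) the iso level is lowered by
  phi(0) * sigma / rEff, with rEff the volume-equivalent radius; this cancels
  the bulk bias while keeping the field, and hence the mesh, smooth. On the
  reference sphere (r = 10 mm, 0.5 mm spacing) the enclosed volume and area
  are then within 0.5% of the analytic values.
* Edge-interpolation parameters are clamped to [0.05, 0.95], which keeps
  marching-tetrahedra vertices away from lattice points and eliminates sliver
  triangles that destabilize curvature fits; the geometric displacement is at
  most a twentieth of a voxel.
* Taubin lambda/mu smoothing (0.5 / -0.53, 10 iterations) suppresses the
  residual staircase without shrinkage.

`principalCurvatures()` fits a quadric height patch over each vertex's ring
neighborhood (default 3 rings) in the outward-normal frame and takes the
shape-operator eigenvalues, corrected by the first fundamental form of the
fitted patch. Three rings average out the irregular vertex distribution of
marching-tetrahedra meshes; on the reference sphere the median mean curvature
is within 1% of 1/r and the Gauss–Bonnet integral within 1% of 4 pi.
Vertices with fewer than five neighbors or an ill-conditioned fit are flagged
unreliable and excluded from all integrals (they enter the surface-exemplar
distribution as "unknown", the indolent end of the ordination).

Surface summary features follow standard definitions. The two bending
energies are the integrals of H^2 and of H^2 - K (both scale-invariant; 4 pi
and 0 on a sphere — the pair is distinguishable by exactly that test).
"Sharp" is the bending anisotropy kappa1 - kappa2, which vanishes on umbilic
(locally spherical) surfaces and grows on ridges and spicules; its formula is
not published, and anisotropy is the natural reading that matches smooth
controls scoring lower. The shape index uses
s = (2/pi) atan((k1 + k2)/(k1 - k2)), +/-1 at umbilic points by the sign of
H and 0 on flat patches. Under the outward-normal convention a convex nodule
is "peak"-dominated and scores the maximal surface SILA; the published sign
convention is not stated, so all assertions in this package are made under
the documented outward convention.

# Exemplars and SILA

Texture exemplars are a dictionary of nine prototype patch classes. The
original trained exemplar values are unpublished, so the package re-derives a
stand-in dictionary: k-means (k = 9, 100 restarts) over four patch
descriptors — window mean HU, SD, mean gradient magnitude, RMS Laplacian —
computed on a synthetic patch library of nine families spanning air-like to
soft-tissue-like attenuation with geometrically increasing heterogeneity,
generated with a fixed seed (`defaultTextureExemplars()` is bit-reproducible).
Descriptors are evaluated over physically sized box windows (radius
round(2 mm / spacing) voxels per axis, ~5 mm at 1 mm spacing) rather than by
resampling to an isotropic grid; this achieves the same fixed physical scale
with one less interpolation. Centroids are ordinated by ascending mean HU and
mapped onto the fixed label order V-R-O-I-Y-P-B-G-C (most indolent to most
aggressive).

Parenchymal classification of the 10 mm shell is rule-based, with
conventional quantitative-CT thresholds (the class names are published, the
thresholds are not): low-attenuation areas at <= -950 / (-950, -910] /
(-910, -856] HU (severe/moderate/mild), ground glass (-700, -500],
reticular and honeycombing surrogates as local-SD > 40 HU voxels in the
(-700, -200] band (honeycombing additionally adjacent to air-density voxels),
normal lung as the remainder. Vessels are soft-tissue-density shell voxels in
(-200, 100]; anything above 100 HU or at/below -1024 HU counts as non-lung
"background" — the literal published meaning of "background" is unstated, and
this non-parenchymal-content reading keeps the partition property (every
shell voxel gets exactly one label, checked exhaustively in the tests).

SILA maps an ordinated exemplar distribution onto [0, 1]:
with cumulative sums F_i over the ordination,
SILA = (1/(K-1)) * sum_{i=1}^{K-1} (1 - F_i)^2 — the squared-CDF
(Cramér–von Mises type) distance from the degenerate fully-indolent
distribution, normalized by K - 1 so the fully aggressive distribution scores
exactly 1 for any K (needed to compare K = 7 and K = 9 scores). The reference
and normalization are this package's choice; they satisfy all the qualitative
requirements (0 and 1 only at the two degenerate extremes, strict increase
under any mass transfer toward the aggressive end). Feature tables report
100 x SILA; the published absolute texture-SILA scale differs (its cohort
mean exceeds 100), so only orderings and contrasts are comparable, never
absolute values. The two fibrosis/emphysema sub-scores use sub-ordinations
(Normal < Ground glass < Reticular < Honeycombing, and Normal < mild <
moderate < severe low attenuation); classes outside a sub-ordination fold
into Normal, so a purely emphysematous shell has fibrosis SILA 0 and vice
versa. Local SILA scores each mesh vertex's geodesic neighborhood (default
radius 3 mm, truncated Dijkstra on mesh edges) and summarizes the per-vertex
scores by mean and skewness.

# Feature panel interpretation

Three catalogue items needed an interpretation, fixed as follows:

* "Minimum enclosing brick" is the PCA-oriented bounding box of the voxel
  world coordinates; the scalar "Minimum Enclosing Brick" is its smallest
  extent and "Maximum Brick length" its largest (which duplicates item
  "Minimum Enclosing Brick x" under the sorted-extents reading; the published
  table prints different means for the two, so their exact construction
  differs in some unstated way).
* Elongation and flatness are natural-log axis ratios ln(b_y/b_x) and
  ln(b_z/b_x) (both <= 0); plain ratios in (0, 1] cannot average to the
  published negative values.
* Sphericity-type ratios (sphericity, sphere fit factor = A^3/(36 pi V^2) =
  sphericity^-3) use the mesh-enclosed volume, so the isoperimetric
  inequality bounds sphericity at exactly 1; the "Volume" feature itself is
  voxel count x voxel volume. HU kurtosis is reported as excess (normal = 0).
  "Morpheme average/skew curvature" are the area-weighted curvedness mean and
  skew, which coincides with the "Average/Skew Curved" pair — one of the two
  published pairs presumably used a different statistic, but no formula is
  given.
* `centroid_z` in extracted tables is the vertical offset from the carina
  landmark (the form in which vertical location enters the classifier);
  centroid_x/y are absolute world coordinates. The 6-level ordinal location
  code is a geometric surrogate (left/right halves x upper/middle/lower
  thirds of the lung bounding box), not an anatomical lobe label.

# Statistical pipeline

Univariate screening reports the rank-formulation (Mann–Whitney) AUC with
midrank ties, the normal-approximation test p-value, and Bonferroni
adjustment min(1, m p) over the m features screened. Stability selection
reruns, 1000 times by default, an L1-penalized logistic regression on a
stratified bootstrap resample of the rows, with the penalty chosen within
each run by 10-fold cross-validated deviance under the one-standard-error
rule — the sparser of the two standard CV conventions, chosen because the
minimizing penalty admits noise features into roughly half the runs, which
defeats the purpose of a 50% frequency threshold. Features selected in at
least half the runs are refit by unpenalized maximum likelihood (the
published per-feature p-values imply an unpenalized refit). Perfect
separation makes that refit invalid and raises an error naming the
separating feature; an opt-in `onSeparation = "ridge"` fallback (lightly
L2-penalized fit, no Wald p-values) exists for small simulated cohorts where
separation is a sample-size artifact.

Internal validation is Harrell's optimism bootstrap: the full procedure —
including any selection step — is repeated on each of B stratified resamples,
and each resample contributes AUC(model_b on resample) minus AUC(model_b on
original). The procedure is a plain function `(table, seed) -> model`, so
what is validated is exactly what was fit; when the stability procedure runs
inside resamples its run count is reduced (100 by default) as a
fidelity/runtime trade-off. The Youden cutoff maximizes sensitivity +
specificity - 1 over midpoints between adjacent distinct scores under the
rule "score >= cutoff is malignant", breaking ties toward higher specificity;
with a single distinct score the cutoff is that score (J = 0). Ablation
refits without each selected feature at a shared seed so all rows see the
same resamples. The cohort filter applies the closed 7–30 mm diameter
interval (a 30.0 mm nodule is included), single-nodule and known-outcome
rules, tallying exclusions by first matching reason. Group tests are Fisher's
exact (two-sided, by the standard rule of summing hypergeometric
probabilities no larger than the observed table's) and the pooled-variance
t-test from summary statistics; the demographics report rounds percentages
half-up to one decimal and p-values to two.

Rows with missing values in selected features are dropped with a logged
count (no imputation; published practice removed individual outliers
per-variable). An optional robust filter (|z| > 8 per feature) is available
through the screening table for audit-style outlier exclusion.

# What the synthetic data emulate — and what they do not

`generatePhantom()` rasterizes a star-shaped solid: an ellipsoid
(`baseRadius` x `axisRatios`) whose radius function carries a band-limited
angular lobulation (`lobulationAmplitude` mm at angular frequency
`lobulationOrder`) plus cone-shaped spicules (count, length; half-angle 0.3
rad) along random directions, filled with Gaussian HU noise (interior
default -200 +/- 30 HU; background per `shellPattern`: normal -800 +/- 30,
ground glass -600 +/- 40, low attenuation -960 +/- 20, reticular -450 +/-
130). The geometry and noise random streams are split per component, so a
spec differing only in spicule count shares its lobulation and background
noise — which is what makes the monotonicity property (more spicules, larger
surface area) testable at a fixed seed. The grid is sized to hold the shape
plus a 12 mm margin; the carina landmark is the mask centroid plus
`carinaOffset`.

`generateFeatureTable()` draws cohort feature tables through a Gaussian
copula: correlated standard normals (preset "block": 0.5 within a feature
category, 0.1 across — inter-feature correlations are unpublished, so these
presets are stand-ins, not estimates) transformed per feature to a Gaussian
or shifted-lognormal marginal moment-matched to the published per-class
mean/SD. Lognormal marginals are used for skewed strictly-positive features
(volume, bending energies, HU kurtosis, vertex counts, ...) where Gaussian
draws would produce impossible negative values; the sphere-fit factor is
shifted by its lower bound 1. Optional clinical covariates (age, pack-years,
sex, smoking) follow the published demographics.

`simulatePhantomCohort()` draws overlapping class morphologies — benign:
near-ellipsoids, mild lobulation, at most two short spicules; malignant:
stronger lobulation, 3–10 spicules of 1.5–5 mm — with radii 3.5–10 mm
(7–20 mm diameters), deliberately overlapping so that no single feature
trivially separates 20-per-class cohorts.

Passing tests on these data show that the geometry, exemplar and validation
machinery is correct and well calibrated, not that the classifier reproduces
clinical performance: the phantoms contain no dose- or kernel-realistic CT
noise, no vessels or pleural attachments in the shell (the vessel and
background features are constant zero on phantom cohorts and are excluded
from selection with a warning), no partial-volume or motion artifacts, and
the cohort simulator's correlations are presets. The published cohort AUCs
(0.94-class numbers) are not reproducible from synthetic data and are not
claimed; all quantitative test anchors are analytic (sphere identities,
enumeration oracles, published contingency tables).

# Problem sizes used by the checks

The acceptance checks run at: sphere r = 10 mm at 0.5 mm spacing (~22k mesh
vertices); support-recovery simulation with 2 informative + 20 noise
features at 400 per class and 200 stability runs; null optimism calibration
at 200 per class, 20 features, B = 100; and a 40-phantom cohort (20 smooth,
20 spiculated at 1 mm spacing) through extraction, 100-run selection and
B = 50 validation. These sizes were chosen to put every estimate's Monte
Carlo error well inside the asserted tolerances.

# Known limitations

DICOM series input is not supported (convert to NIfTI first). The exemplar
dictionary is a reproducible stand-in, not the original trained one, so
absolute SILA values are not comparable to published tables. Surface features
assume a closed genus-0 lesion; plate-like or cavitating lesions violate
that. The shell's parenchymal features are only as good as the HU threshold
rules; no vessel-tree segmentation is attempted. The NIfTI header stores the
spatial transform in float32, so spacing/origin round-trip to ~1e-7 relative
precision.
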