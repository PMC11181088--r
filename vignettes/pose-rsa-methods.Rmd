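---
title: "Methods: representational similarity analysis of body pose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representational similarity analysis of body pose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poseRSA)
```

## The question and the modelling strategy

Does visual cortex carry information about the three-dimensional posture of
a seen body beyond its retinal projection, and beyond the viewpoint it is
seen from?  poseRSA operationalizes this question with representational
similarity analysis (RSA): each candidate representation of a body is
turned into a representational dissimilarity matrix (RDM) over a stimulus
set, and each RDM is correlated with the dissimilarity structure of
multi-voxel fMRI response patterns.  A region whose neural RDM correlates
with the view-independent 3D pose RDM — and keeps doing so when the
view-dependent and viewpoint RDMs are partialled out — carries intrinsic
pose information.

## Pose parameterizations and their dissimilarities

A pose is a list of $K = 19$ labelled 3D joint locations
$p = [J_1, \dots, J_K]$ (ankles through ears; fingers, toes and jaw
excluded) together with a global body rotation $R \in SO(3)$.  Four
representations are derived from it:

* **view-dependent 3D**: the raw joints $J_k$ in the viewer's frame;
* **view-dependent 2D**: orthographic projection, $J_k^{(2d)}$ = the first
  two coordinates (depth discarded; no camera intrinsics are modelled);
* **view-independent 3D**: $J_k^{(vi)} = R^{-1} J_k$, undoing the global
  rotation so that two poses differing only in viewpoint coincide.  No
  further centering or scaling is applied — the joints are assumed to be
  expressed in a common body-model frame already;
* **viewpoint**: the global rotation itself, stored as a unit quaternion.

Pose dissimilarity is the mean per-joint position error
$d(p_i, p_j) = \frac{1}{K}\sum_k \lVert J_{ik} - J_{jk}\rVert_2$, the
standard metric of the 3D pose-estimation literature, applied to whichever
joint set the representation defines.  Viewpoint dissimilarity between unit
quaternions is $d_v(q_i, q_j) = \cos^{-1}(\lvert q_i \cdot q_j \rvert)$.
The absolute value is a deliberate choice: $q$ and $-q$ encode the same
rotation (the double cover of $SO(3)$), so without it the metric would
depend on an arbitrary sign convention.  With it, the metric is well
defined, bounded by $\pi/2$, and invariant to independent sign flips of
either argument; the dot product is clamped to $[-1, 1]$ so identical
rotations give exactly zero.  The per-joint rotation control model averages
the same metric over $K$ per-joint quaternions.  Quaternions are stored
$(w, x, y, z)$ with $w \ge 0$ canonical sign so serialized rotations are
deterministic.

Model RDMs are min–max normalized to $[0, 1]$ over the off-diagonal before
RSA (the zero diagonal is excluded from the min/max — including it would
make the normalization depend on whether the smallest dissimilarity is
attained or not).  A constant off-diagonal raises an error rather than
returning zeros: a flat RDM would silently poison every downstream
correlation with NaNs.

## Stimulus selection and control models

Stimulus filtering follows the COCO 17-keypoint annotation dialect: an
image qualifies if it has exactly one annotated person whose 12 limb
keypoints (shoulders, elbows, wrists, hips, knees, ankles) all carry a
visibility flag other than "not annotated".  Occluded-but-annotated counts;
face keypoints are ignored because they are frequently missing for small
figures.

Three body-geometry controls summarize where and how large the body is:
the person bounding-box center in polar coordinates about the image center
(angle and distance) and the segmentation area as a fraction of image area.
Angle dissimilarity is the circular difference wrapped to $[0, \pi]$ —
polar angle is periodic, and an unwrapped difference would call 170° and
−170° maximally different when they are 20° apart.  At the exact image
center the angle is undefined and set to 0 by convention (flagged in the
output) to avoid NaN propagation.  Distance units are pixels by default;
nothing downstream depends on the unit because RDMs are normalized per
subject.  Feature-based controls accept precomputed embeddings (one vector
per image) and use either Euclidean distance on unit-L2-scaled vectors
("normalized embeddings") or $1 - r$ on raw vectors; extraction of such
embeddings is outside this package's scope.

## From betas to neural RDMs

Trial responses (GLM betas) for the same image are averaged, then each
voxel is z-scored across images so every voxel contributes equally to the
distance; voxels constant across images cannot be standardized and are
excluded (recorded, not silently dropped).  The neural RDM is
$1 - r_{\text{Pearson}}$ between item patterns.  RDM-to-RDM correlation is
Pearson on the strictly-lower-triangle vectors; a single fixed
vectorization convention keeps results bit-stable.  Partial RSA
residualizes both triangles on the control triangles by least squares with
an intercept and correlates the residuals — algebraically the standard
partial correlation, but numerically stable with several controls.
Correlation type is Pearson throughout.  Fisher's $z = \operatorname{atanh}(r)$
is applied before group statistics, with $\lvert r \rvert$ clipped at
$1 - 10^{-12}$ so a degenerate searchlight cannot inject infinities.

## Searchlight mapping

Searchlights are fixed-count spherical neighborhoods: for every in-mask
voxel, the 100 nearest in-mask voxels by center-to-center distance, the
convention of the common MVPA toolboxes.  At 1.8 mm isotropic voxels, 100
voxels occupy the volume of a sphere of radius
$(3 \cdot 100 \cdot 1.8^3 / 4\pi)^{1/3} \approx 5.2$ mm, reported by
`equivalent_radius()`.  Fixed count rather than fixed radius keeps the
pattern dimensionality constant at mask edges (the neighborhood reaches
farther instead of shrinking).  Equal-distance ties are broken
lexicographically by voxel index, with squared distances computed in exact
integer grid arithmetic, so neighborhoods are deterministic across
platforms.  Degenerate centers (zero-variance patterns) get NaN and are
excluded from group statistics.

## Group inference

Subject Fisher-z maps are tested against zero with a one-tailed one-sample
t test per voxel (positive model correlation is the hypothesis; sd uses
the $n-1$ denominator; zero-variance voxels give NaN, never $\pm\infty$).
Family-wise error is controlled by a max-sum cluster permutation test:
voxels with one-tailed $p <$ `initial_p` (default 0.001) are clustered by
26-connectivity (configurable: 6/18/26), each cluster's statistic is its
sum of t values, and the observed statistics are compared with the null
distribution of the *maximum* cluster sum over random whole-map sign flips
of subjects — the standard exchangeable null for one-sample tests of maps
symmetric about zero.  Cluster p-values use the $(1 + k)/(1 + N)$
estimator, which is unbiased and never exactly zero.  Cluster formation
uses signed positive t only, consistent with the one-tailed hypothesis.
Defaults are 10,000 permutations and `initial_p` 0.001; the validation
experiments use 500 permutations, which is ample for $p \le 0.01$
decisions.

## ROI analysis and the noise ceiling

ROI RSA applies the identical pattern pipeline to all voxels of an ROI
(optionally pre-selected by a localizer-t threshold; the threshold is
strict, `t > 8.0` keeps 8.1 but not 8.0).  The noise ceiling answers "what
correlation could a perfect model achieve given the trial-to-trial noise?"
for two-repeat designs:

1. noise covariance $\Sigma_n$ from half-differences of the two repeats
   per image ($\operatorname{cov}(x_1 - x_2)/2$);
2. signal covariance $\Sigma_s$ = covariance of per-image means minus
   $\Sigma_n/2$, eigenvalue-floored at zero (the floor count is logged);
3. a scalar on $\Sigma_s$ calibrated by bisection (to $10^{-3}$) so that
   the split-half reliability of simulated RSMs matches the empirical
   split-half reliability — calibration targets the RSM-to-RSM split-half
   correlation (not per-entry reliability), a concrete choice this package
   documents rather than asserts as unique; common random numbers across
   bisection evaluations keep the calibration curve monotone;
4. each Monte Carlo simulation draws item signals and two noisy repeats,
   pushes both through the real pipeline (average, z-score, correlation
   similarity), and correlates the noiseless with the noisy similarity
   triangle; the ceiling is the mean over `n_sim` (default 1,000)
   simulations, seeded.

On fully synthetic data from known Gaussians the blind estimate tracks
the oracle ceiling computed with the true generating distributions; the
tests assert agreement within 0.05 and the acceptance run reports the
measured gap.

## The synthetic-data generator

The generator exists so every stage is testable without fMRI or image
downloads; its defaults are the package's study conditions and are not
tuned per test.

* **Poses**: a fixed template skeleton (standing figure, ~1.7 units tall)
  jittered per image with Gaussian joint noise (`jitter_sd` 0.1, about
  10 cm per coordinate — enough articulation to spread the MPJPE range
  without breaking body proportions), then rotated by a uniform random
  rotation (normalized 4D Gaussian quaternions are exactly uniform on
  $SO(3)$).  Only relative geometry matters to every metric, so the
  template proportions are arbitrary but fixed.
* **Keypoint records**: exactly `round(n * fraction_valid)` images qualify
  under the stimulus filter; the rest fail by a randomized known mechanism
  (extra person, one missing limb flag, or boundary truncation).
* **Responses**: the planted dissimilarity is the weighted sum of
  normalized input RDMs.  Because the neural readout is correlation
  distance on z-scored patterns, the achievable item Gram matrix is
  centered, which forces the realized correlation matrix $C$ to have a
  positive null vector (the item pattern norms).  The generator exploits
  this instead of fighting it: it demeans the target off-diagonals
  (Pearson RSA is affine invariant), solves
  $(1-a)s + a n \mathbf{1} = b \tilde{D} s$ for the pattern norms $s$ and
  mixing constant $a$, takes the planted gain $b$ as large as positive
  semidefiniteness of $C = (1-a)I + aJ - b\tilde{D}$ allows, and embeds
  the resulting Gram in a random voxel frame orthogonal to the constant
  vector.  Givens rotations (which act on the right and cannot change the
  item Gram) then equalize voxel variances in alternation with
  row-centering and re-projection onto the exact Gram, so the pipeline's
  per-voxel z-scoring is a near-no-op.  The realized noiseless readout
  correlates with the target at ~0.997 or better for 60 items; the value
  is checked at generation and stored.  Classical-MDS embedding of the raw
  distances was rejected because the correlation-distance readout
  double-centers and renormalizes the geometry, capping the realized
  fidelity near 0.7.  Trial noise is isotropic Gaussian on the unit
  per-voxel signal scale, so `noise_sd = 0.5` means noise at half the
  signal SD.
* **Subject maps**: shared spherical blob (hard sphere, amplitude in noise
  SD units) plus independent Gaussian noise; a null spec gives
  exchangeable maps symmetric about zero, exactly the sign-flip null.

What the generator does *not* emulate: spatial noise correlations,
subject-level anatomical variability, hemodynamic structure, session
effects, and realistic (non-Gaussian) pose distributions.  Passing tests
therefore demonstrate correctness of the algorithms under their stated
assumptions, not robustness to every property of real fMRI data.

## Numerical and design choices

* Rotation matrices are validated to orthonormality and $\det = +1$ at
  $10^{-6}$; quaternion round-trips are exact to $10^{-8}$ (Shepperd's
  branch selection avoids the ill-conditioned trace formula near 180°
  rotations).
* Subsetting an RDM to a subject's stimulus subset clears the normalized
  flag; renormalize per subject before RSA.
* When a target RDM is linearly dependent on the controls, partial RSA
  raises a collinearity error (residual variance below $10^{-12}$) rather
  than returning noise.
* Problem sizes of the validation experiments: 200 null replicates of
  8 subjects on a 20³ grid with 500 permutations for the type-I
  calibration; 100 replicates of 60 poses × 300 voxels for model
  recovery; 100 items × 40 voxels × 500 simulations for the ceiling
  benchmark.  These sizes give Monte Carlo error comfortably inside the
  asserted bands while keeping a full validation run in minutes.

## Known limitations

* The pipeline consumes poses; reconstructing them from images (3D mesh
  regression) is out of scope, as are feature extractors for the
  embedding controls and GLM beta estimation.
* Volume-space only; surface searchlights and nonlinear spatial
  normalization are input contracts, not implemented here.
* The planted-geometry construction requires more voxels than items and
  plants geometry in correlation space; it does not emulate the absolute
  response amplitudes of real regions.
* The noise-ceiling estimator is specified for exactly two repeats per
  image (the design it models); other repeat counts are rejected rather
  than approximated.
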