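---
title: "Methods: cranio-cerebral correspondence in the developing infant head"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cranio-cerebral correspondence in the developing infant head}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniocorr)
```

## The question

Scalp-based positioning systems (the international 10-20 system and its
10-10 refinement) are the only practical frame of reference for infant
EEG and fNIRS, where MRI-based normalization is often impossible. The
analyses in this package ask whether that frame stays anchored to the
underlying cortical macroanatomy while the brain and head grow through
the first two years: how the relative positions of cortical landmarks
change with age, and whether that change is small compared to the pitch
of the 10-10 grid.

All coordinates live in the AC-PC frame: origin at the midpoint of the
anterior and posterior commissures, +y anterior along the AC-PC line,
+z superior in the midsagittal plane, +x left-to-right, units mm
(`acpc_align()` constructs the frame by Gram-Schmidt from AC, PC and a
midsagittal point and is invariant to any rigid motion of its inputs).

## Virtual 10-20/10-10 positioning

Scalp positions are constructed purely from surface geometry and the
four fiducials Nz (nasion), Iz (inion), AL/AR (pre-auricular points):

* **Curves are plane sections.** Every construction curve is the
  intersection of the scalp mesh with the plane through its two
  endpoints and a third anchor; when the closed section offers two
  sub-arcs between the endpoints, the one passing nearest the third
  anchor is taken. This reproduces "over-the-vertex" curves
  unambiguously and follows the lineage of the deterministic
  ("unambiguously illustrated") 10-10 construction. True surface
  geodesics are deliberately out of scope.
* **Cz is a fixed point.** Starting from the topmost mesh vertex, Cz is
  alternately re-estimated as the 50% point of the Nz–Cz–Iz arc and of
  the AL–Cz–AR arc until it moves less than 0.1 mm (default; at most 50
  iterations). On left-right symmetric heads the iteration converges in
  one or two steps.
* **Subdivision.** The midline and central coronal curves are divided
  at 10% steps; the circumferential ring through Fpz, T3, Oz, T4 at
  5%-of-ring steps (each quarter is parametrized by arc length between
  its anchors, so the anchors sit exactly at 0/25/50/75%); transverse
  curves joining a left ring point, a midline point and a right ring
  point are divided into 4 (10-20) or 8 (10-10) equal arcs, with the
  midline point as the plane's third anchor. The label/fraction table
  (`craniocorr:::montage_definitions()`) is data, not code.
* The 10-20 montage used for head shape analysis has exactly 25
  positions: the 19 classic electrodes plus Fpz, Oz and the four
  fiducials. The older temporal names (T3/T4, T5/T6) are used.

Numerical safeguards: vertices falling exactly on a section plane are
nudged by a relative 1e-12 so every crossed triangle contributes exactly
one chord; chords are keyed by mesh edge, so chaining needs no
coordinate hashing; arc anchor points must snap to the section within
half the median edge length (default mesh tolerance for point-on-surface
checks is 0.5 mm).

## Procrustes shape analysis

Configurations (20 cortical landmarks: ids 7–15 and 20 for each
hemisphere; or the 25 scalp positions) are fitted by generalized
Procrustes analysis: centering, scaling to unit centroid size, and
iterated optimal proper rotation to the running consensus (partial
Procrustes — the paper-style pipeline scales by centroid size only, with
no additional rotational rescaling; convergence tolerance 1e-8, at most
100 iterations). Reflections are never used, so a mirrored configuration
is *not* silently undone.

Because the consensus orientation is mathematically arbitrary, the
converged solution is put in a canonical frame: the consensus' principal
axes are aligned with the coordinate axes, with signs fixed by requiring
the largest-magnitude landmark projection on each of the first two axes
to be positive (signs must be derived from landmark projections — an
intrinsic quantity — to be independent of the input frame). This makes
`gpa()` deterministic and invariant, to 1e-6, under input reordering and
arbitrary similarity transforms of any input.

Shape PCA operates on the mean-centered flattened Procrustes
coordinates; each component's sign is fixed by making its
largest-magnitude loading positive. PC scores are regressed on age with
the same exact Pearson test used for the ratio table. Tangent-space
projection is omitted: the shape variation here is small (Procrustes
distances well below 0.1), where the tangent approximation and the shape
sphere coincide to well beyond the reported precision.

## Distance-ratio statistics

For a landmark *b* between reference extremes *a* (frontal pole or
vertex) and *c* (occipital pole or brain base), the statistic is
`d(a,b)/d(b,c)` — direct 3-D distance, or distance after projecting all
three points to the sagittal (x = 0) or coronal (y = 0) plane, fixed per
table row. A declining ratio means the landmark shifts toward *a*
(anteriorly, or dorsally for the height rows). Junction landmarks
(8, 9, 10, 11, 12, 20) are first moved laterally — along ±x, preserving
y and z — to the outermost cortical surface crossing, removing their
depth variability; the lateral ray is cast from the midsagittal line so
that points that noise pushed slightly outside the surface still adjust
inward, with a nearest-point fallback (logged) when the (y, z) location
leaves the surface silhouette entirely.

Correlations with age use Pearson's r with the exact two-tailed p from
`t = r sqrt(n-2)/sqrt(1-r^2)` on n−2 degrees of freedom. P-values are
printed at 3 decimals (round-half-even) with raw values retained. No
multiple-testing correction is applied, matching the descriptive use of
the table. Dependent landmarks 16–19 are generated on the coronal slice
of landmark 11 and are excluded from shape analysis; landmark 19 is
excluded from the ratio table and retained in the transfer.

## Three-vector transfer to a template scalp

With M the midpoint of AL–AR and L1–L3 the three neighboring 10-10
positions of a cortical point CP, the coefficients (a1, a2, a3) solve
`CP − M = a1 (L1 − M) + a2 (L2 − M) + a3 (L3 − M)` exactly (residual
≤ 1e-9 mm). Applying the same coefficients to the template's
corresponding vectors yields the template-space point, which is then
back-projected onto the template scalp.

Three design points were genuinely open and are resolved as follows:

* *"Linearly enlarging the three coefficients"* is implemented as one
  common scale factor, i.e. extending the ray from M through the point
  to its outermost scalp intersection — the only interpretation that
  preserves the direction of the M-ray; independent per-coefficient
  scaling would be underdetermined.
* *Neighbor selection* is nearest-by-Euclidean with an independence
  guard: candidates are accepted in distance order while the vector set
  {Li − M} keeps a condition number below 1e6, so a degenerate (e.g.
  coplanar-with-M) candidate is passed over for the next-nearest
  independent one. Distances are ranked against the cortical point's own
  scalp projection (the M-ray extended to the subject's scalp), so deep
  landmarks select lateral, not vertex, neighbors.
* *Exclusions are parameters.* Subjects without a valid montage are
  excluded with a logged reason rather than hard-coding a count.

Dispersion per landmark is summarized as distances from the per-landmark
centroid with type-7 quartiles and Tukey whiskers (largest value below
Q3 + 1.5 IQR, smallest above Q1 − 1.5 IQR), and compared against the
montage's nearest-neighbor distances.

## The synthetic cohort generator

The generator provides ground-truth-known data in place of an infant MRI
cohort (default: 16 subjects, ages spread over 3–22 months with jitter).

* **Head model.** Brain surfaces are superellipsoids
  (`|x/a|^p + |y/b|^p + |z/c|^p = 1`, squareness p = 2.5) with semi-axes
  growing linearly in age; the scalp is the brain offset outward by 8 mm;
  fiducials sit at the scalp's parametric extremes. Default dimensions
  (12-month brain length ≈ 138 mm) and growth slopes (length 0.90 >
  height 0.55 > width 0.35 mm/month per semi-axis) are configurable
  assumptions chosen to be anthropometrically plausible, not literature
  values; their ordering encodes that infant brain growth is most
  prominent in length, then height, then width.
* **Landmarks.** The 20-per-hemisphere landmark vocabulary is placed at
  fixed unit directions mapped onto the surface; landmarks 16–19 are
  computed on the coronal slice of (the observed) landmark 11 at fixed
  height fractions, mirroring their slice-dependent definitions.
* **Age drifts.** Selected landmarks drift along the surface tangent:
  anterior drifts of 0.55 mm/month on landmarks 8, 9, 10, 12, a dorsal
  drift of 0.50 mm/month on 14, and a right-only ventral drift of 0.50
  mm/month on 18. The rates were calibrated once so that the ratio-age
  correlations over a 16-subject cohort average |r| ≈ 0.65–0.72 at the
  default noise level (measured over 40 independent cohorts during
  development, then frozen); at that effect size the sign is detected
  (negative r, p < 0.05) in ≈ 91% of replicates.
* **Noise.** Landmark localization noise is isotropic Gaussian with
  σ = 2.16 mm per coordinate. Two independent realizations of the same
  landmark then differ by 4σ/√π ≈ 4.87 mm on average, reproducing a
  typical inter-rater mean distance for manual infant-MRI landmarking.
  The noise is Gaussian, so it does not reproduce the heavy-tailed
  inter-rater SD seen with occasional gross rater disagreements.
* **Individual anatomy.** Per-subject multiplicative semi-axis factors
  (lognormal, CV 3%) keep the cohort from being a pure one-parameter
  age family. Set `individual_cv = 0` for strictly age-determined heads.

**The null model used in tests** sets drift to zero, individual
variation to zero, and growth *proportional* to the base semi-axes, so
heads of different ages are exact similarity transforms of each other.
Under that null every distance ratio and every Procrustes shape is
exactly age-invariant — equal additive slopes would not suffice, since
adding the same millimeters to unequal axes changes shape. With noise
switched on, this null is the reference for the type-I error of the
ratio-age test (≈ 5% by construction).

**What passing tests do and do not show.** The generator emulates
age-dependent size and shape change, landmark drift, rater noise and
individual scale variation — the features the statistics consume. It
does not emulate gyrification, cortical folding variability, fiducial
placement error, asymmetric head shapes or MRI artifacts. In particular,
the superellipsoid family has only three shape parameters, so after
Procrustes scaling the scalp configurations span a two-dimensional shape
space: head-shape PCA on synthetic cohorts concentrates all variance on
two components, unlike real heads. Passing the suite therefore validates
the algorithms and their statistical calibration, not the anatomical
realism of any particular dataset.

## Problem sizes and runtime choices

Tests run the full pipeline at the study's natural size (16 subjects,
meshes of ~5000 faces, both montage systems) and use reduced meshes
(48 × 24) where only topology matters. Simulation-based checks use 1200
null cohorts for the type-I error (99% binomial CI around 5%), 200
replicate cohorts for drift detection, and 40 cohorts for the
calibration measurements reported above; all are landmark-only
simulations (no meshes), which makes them cheap. The acceptance script
re-runs the complete analysis in well under a minute.

## Known limitations

* Plane-section arcs approximate geodesics; on strongly non-convex
  scalps the section can fragment, which the arc extractor reports
  rather than repairs.
* The head shape space of the generator is low-dimensional (see above).
* The Gaussian noise model matches the inter-rater mean but not its SD.
* Partial (unit-size) Procrustes is the only scaling offered; whether a
  full-Procrustes (cos-ρ) rescaling would materially change results for
  such small shape variation is flagged but not implemented.
* The ratio table's interpretation column encodes sign conventions
  (declining ratio = anterior/dorsal shift); PC-score signs follow the
  package's deterministic convention and may differ from other software.
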