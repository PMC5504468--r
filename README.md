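# craniocorr

Cranio-cerebral correspondence and virtual 10-10 positioning for the
infant head.

## What this package is for

Transcranial neuroimaging of infants (EEG, fNIRS) places sensors on the
scalp by the international 10-20/10-10 system and must assume that scalp
positions keep pointing at the same cortical structures while both the
brain and the head grow rapidly over the first two years. `craniocorr`
implements the complete analysis needed to examine that assumption:

1. **Virtual 10-20/10-10 positioning** (`place_cz()`, `place_montage()`):
   the deterministic arc-subdivision construction of scalp positions on a
   triangulated head surface from the four cranial fiducials Nz, Iz, AL,
   AR. Cz is the fixed point that simultaneously halves the nasion-inion
   and left-right pre-auricular arcs; the midline and central coronal
   curves are subdivided at 10% steps, the circumferential ring through
   Fpz/T3/Oz/T4 at 5%-of-ring steps, and the remaining positions come
   from transverse curves split into equal arcs.
2. **Generalized Procrustes shape analysis** (`gpa()`, `pca_shapes()`,
   `regress_scores_on_age()`): landmark configurations are translated to
   a common centroid, scaled to unit centroid size
   (`CS = sqrt(sum_i ||x_i - x_bar||^2)`), and rotated by optimal proper
   rotations to a consensus; shape-space PCA and Pearson regression of PC
   scores on age quantify developmental shape trends.
3. **Topological-relationship ratios** (`table1_analysis()`, `ratio()`,
   `pearson_with_p()`): for a landmark b between two reference extremes a
   and c, the ratio `d(a,b)/d(b,c)` (direct, or after sagittal/coronal
   projection) is correlated with age; two-tailed p-values come from
   `t = r sqrt(n-2)/sqrt(1-r^2)` on n-2 df. Junction landmarks are first
   adjusted laterally onto the cortical surface to remove depth
   variability.
4. **Cortical landmark transfer** (`transfer_cohort()`, `decompose()`,
   `recompose()`, `backproject_to_scalp()`, `dispersion()`): a cortical
   point CP is written as
   `CP = M + a1 (L1 - M) + a2 (L2 - M) + a3 (L3 - M)`,
   where M is the pre-auricular midpoint and L1-L3 the three neighboring
   10-10 positions; the coefficients are re-applied in a template head's
   montage and the result is back-projected along the M-ray onto the
   template scalp. Cross-subject dispersion per landmark is summarized by
   box-and-whisker statistics and compared with the montage's
   nearest-neighbor pitch.

Because infant MRI cohorts cannot be redistributed, the package ships a
**synthetic cohort generator** (`growth_model()`, `make_cohort()`):
superellipsoid heads with age-dependent anisotropic growth (length >
height > width), configurable anterior/dorsal landmark drifts, and
rater-style localization noise calibrated so the mean inter-rater
landmark distance is about 4.87 mm. Every downstream stage is exercised
and tested against this generator's known ground truth.

## Worked example

```r
library(craniocorr)

report <- run_pipeline(pipeline_config(seed = 1))
print(report)
```

```
Cranio-cerebral correspondence pipeline report
  cohort: 16 subjects; seed 1; template S08
  cortex PCA: 25.9%/9.6%/8.7%/8.1%; PC1-age r = -0.88 (p = 0.000)
  head PCA:   77.5%/22.5%/0.0%/0.0%; PC1-age r = -0.76 (p = 0.001)
  ratio table: 26 rows, 13 with p < 0.05
  dispersion: median of medians 3.6 mm; montage NN median 19.3 mm
```

Reading this: the synthetic cohort's cortical shape has a leading
principal component strongly correlated with age (the injected anterior
drifts plus anisotropic growth; PC sign is a fixed package convention),
the distance-ratio table flags the drifting landmarks (negative r for
the anterior drifts on landmarks 8, 9, 10, 12), and the per-landmark
scatter of cortical landmarks transferred onto the template scalp
(median 3.6 mm) stays far below the ~19 mm spacing of neighboring 10-10
positions — scalp-based positioning remains a stable frame of reference
while the head grows.

Individual stages are just as usable on their own:

```r
s  <- make_subject(growth_model(), age_months = 12, subject_seed = 1)
mo <- place_montage(s$scalp, s$fiducials, "10-20")
nrow(mo)                      # 25 positions
fit <- gpa(configurations(cohort_landmarks(make_cohort(growth_model(),
                                                       meshes = FALSE)),
                          "cortex"))
summary(fit)
```

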