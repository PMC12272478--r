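---
title: "Voxel-wise dose-response mapping: model, methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise dose-response mapping: model, methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `drmap`, the
geometric and numerical choices made in its implementation, and the
design and limitations of the synthetic cohort generator. It is written
for a reader who wants to audit the methodology, not just call the
functions; the README covers the quick-start path.

## 1. The problem

After radiotherapy for prostate cancer, parts of the bladder and rectum
receive high incidental dose, and some patients develop urinary or
bowel toxicity. Classical normal-tissue models reduce the organ dose
distribution to scalar summaries (mean dose, dose-volume points) and so
cannot ask *where* on the organ surface dose matters. Voxel-wise
dose-response mapping keeps the spatial information: each patient's
organ surface is unwrapped to a common 2D grid, dose is compared
voxel by voxel between patients with and without toxicity, and
multiple-comparison-corrected significance maps localize candidate
high-risk subregions.

A complication specific to pelvic toxicity endpoints is that many
patients report symptoms *before* treatment. Counting them as
radiation-induced events inflates the event group with dose-unrelated
cases. The package therefore implements two labelling rules and reports
their agreement:

* **uncorrected** — event if the maximum follow-up grade (12 or 24
  months) reaches grade ≥ 1;
* **baseline-corrected** — the baseline grade is first subtracted from
  the maximum follow-up grade; only an *increase* over baseline counts.

Corrected events are a subset of uncorrected events by construction
(subtracting a non-negative baseline can only lower the adjusted
grade), and the test suite enforces this invariant exhaustively.

## 2. Dose-surface maps

### Bladder: spherical unwrapping

`unwrap_bladder_spherical()` casts rays from the organ's volume-weighted
centre of mass. The polar angle θ runs from 0° (superior pole, row 1)
to 180° inclusive in 2° steps — 91 rows; the azimuth φ runs on the
half-open circle [0°, 360°) in 4° steps — 90 columns, with no
duplicated seam column. This fixes the map contract at 91 × 90 = 8190
voxels. φ = 0 is anterior and φ increases towards the patient's left,
so the landmark columns are anterior 1, left ≈ 23, posterior ≈ 46,
right ≈ 68 (`dsm_axes()` is the single authoritative statement of these
conventions).

For each direction the surface radius is found by bisecting a
point-in-organ predicate to 0.1 mm. The predicate interpolates per-slice
radial profiles (720 angular samples per slice) linearly in both slice
position and angle; this assumes the organ is star-shaped about the
centre of mass, which holds for bladder-like shapes. Dose at the surface
point is read from the 3D grid by trilinear interpolation
(`interp_trilinear()`), which is exact for affine fields — one of the
oracle tests exploits exactly that property.

### Rectum: cylindrical unwrapping with a posterior cut

`unwrap_rectum_cylindrical()` works slice by slice: rays are cast in the
axial plane from the slice centroid, and the dose is sampled where each
ray crosses the contour polygon (analytic ray-segment intersection, no
bisection needed in-plane). The angular origin places the cut at
posterior: columns sweep from just left of posterior through the
patient's right, anterior at the map's central column, the patient's
left, and back to posterior. Rows are slices, inferior to superior.
Slices whose centroid falls outside their own polygon (crescent shapes)
cannot be unwrapped directly; their rows are filled by linear
interpolation between the nearest unwrappable neighbours and are marked
invalid when no such pair exists. The centroid-inside test uses
`mgcv::in.out`, a vetted point-in-polygon implementation, rather than a
hand-rolled crossing count.

Because patients differ in rectum length, the raw slice-by-angle map is
resampled to the standard 91 × 90 grid by `normalize_dsm()`. The
resampling is bilinear on the 2D lattice. Validity is conservative: an
output voxel is valid only if *all* contributing input voxels are valid
(the interpolated validity indicator must be 1 within 1e-9), so
interpolation never manufactures dose where a patient had none.

### Manual exclusions

`apply_exclusion_mask()` removes voxels from the valid mask without
touching dose elsewhere — the mechanism for masking known unwrapping
artifact zones (e.g. near the bladder trigone). Exclusions are counted,
never silent.

## 3. Fractionation correction

Physical dose is converted to the equivalent dose in 2 Gy fractions
with the linear-quadratic model,

$$\mathrm{EQD2} = D\,\frac{d + \alpha/\beta}{2 + \alpha/\beta},
\qquad d = D/n,$$

applied voxel-wise with the patient's fraction count
(`eqd2_dsm()`). The default α/β is 1 Gy, appropriate for late urinary
toxicity; `eqd2(69, 32, alpha_beta = 2)` returns 71.70 Gy, a standard
worked example used as an exact test anchor. The voxel-wise application
assumes every voxel received its dose in the same number of uniform
fractions — exact for single-plan treatments, an approximation when
boost phases change the spatial distribution mid-course.

## 4. Voxel-wise inference

### Statistic maps

`welch_tmap()` computes, per voxel, the Welch (unequal-variance) t
statistic between the event and non-event groups; positive t means the
event group received more dose. `mannwhitney_map()` is the rank-based
alternative, reporting the raw Mann-Whitney U and its tie-corrected
standardized value z so that both statistics flow through the same
thresholding machinery. A Shapiro-Wilk screen (`shapiro_screen()`)
reports how non-normal the per-voxel dose distributions are; it is
informative only — the Welch map is computed regardless, on
central-limit grounds at the group sizes involved.

Voxels where the statistic is undefined (dose constant within both
groups) are removed from the valid mask rather than epsilon-padded;
significant-voxel counts are therefore always counts over analysable
voxels.

### Family-wise error control

With 8190 correlated tests, per-voxel p-values are meaningless without
correction, and the spatial correlation makes Bonferroni hopelessly
conservative. `permutation_tmax()` uses the maximum-statistic
permutation method: outcome labels are reshuffled (preserving the event
count), the whole map recomputed, and the maximum over valid voxels
recorded per permutation. The observed map is thresholded at the 95th
percentile of this Tmax distribution, which controls the probability of
*any* false-positive voxel at 5% while automatically adapting to the
correlation structure.

Numerical choices:

* **Batch computation.** All permutations are evaluated with one matrix
  product per moment (a B × n membership matrix times the n × V dose
  matrix), not a loop over `t.test` calls; 1000 permutations of a
  400-patient × 8190-voxel cohort take seconds.
* **Nearest-rank percentile.** The threshold is the k-th smallest of
  the B sorted Tmax values with k = ⌈p/100 · B⌉ — the 950th of 1000.
  This is deterministic and avoids the interpolation ambiguity of
  `quantile()`'s nine types. (The arithmetic is rounded before the
  ceiling so binary floating point cannot push k up by one.)
* **Two tails, reported separately.** Tmax gives the upper threshold;
  the per-permutation minimum (Tmin) gives a lower threshold for
  "events received *less* dose" associations. `tails` selects which
  masks count as significant downstream; the calibration analyses in
  this package use the upper tail only.
* **Determinism.** The permutation seed is an explicit argument, and
  `run_drm_analysis()` derives per-analysis seeds from one master seed
  (`patient_seed()`), so a full run is reproducible bit for bit.

### Calibration evidence

`simulate_null_cohort()` generates exchangeable-null cohorts — smooth
correlated dose fields (kernel-smoothed Gaussian noise over a fixed
mean-dose gradient) with labels drawn independently of dose — on a
reduced 20 × 20 grid so that hundreds of replicates are cheap. Across
400 such cohorts (60 patients each, 1000 permutations, upper tail),
the fraction with at least one significant voxel estimates the realized
family-wise error; the acceptance suite requires it to lie within
0.05 ± 0.025 (the binomial 95% band at 400 replicates), and
`scripts/acceptance.R` recomputes it from the installed package.

### Comparing the two labelling methods

For each endpoint analysed under both rules, `compare_methods()` reports
event counts, significant-voxel counts, and the Dice similarity
coefficient DSC = 2|A∩B| / (|A| + |B|) of the two significance masks.
When both masks are empty the DSC is defined as 0 — "no demonstrated
overlap" — keeping the coefficient in [0, 1] without NaN propagation;
this matches the convention of reporting DSC = 0 when one method finds
nothing.

## 5. The synthetic cohort generator

Real dose-toxicity cohorts are not redistributable, so the package
ships a generator whose population statistics follow published
prostate-radiotherapy study conditions and whose dose-response is
*planted*, i.e. known by construction. It exists for method validation:
every stochastic claim in the test suite is a claim about recovery of a
known truth.

### Geometry

Bladders are star-shaped blobs with lognormal volume
(mean 162.9 cm³, SD 123.8 cm³ — the heavy right tail of real bladder
filling), mild aspect jitter, and low-order harmonic surface
perturbations. Rectums are tubes with normally distributed length
(97 ± 13 mm), slice-wise eccentricity, and a gentle anterior bow.
Analytic phantoms (`phantom_sphere_contours()`,
`phantom_tube_contours()`) live alongside them for oracle tests.

### Dose

`generate_dose()` emulates a prostate plan: an ellipsoidal target
(prescription drawn from 71.4 ± 6.7 Gy, fractions from 34 ± 6.7) is
anchored to the postero-inferior bladder wall or the anterior rectal
wall with a fixed 15 mm overlap, dose falls off sigmoidally (6 mm
scale) with distance from the target surface to a 25% dose bath, and a
smooth cosine modulation (three plane waves, 4-10 cm wavelengths, 6%
amplitude) adds spatially structured per-patient variation. The result
is not a treatment-planning simulation; it is a field with the right
scale, gradients and inter-patient variability to exercise the
pipeline.

### Toxicity

Baseline toxicity is Bernoulli (default prevalence 0.2). The follow-up
event is logistic in the planted region's **dose excess** — the mean
EQD2 over the planted subregion minus the patient's whole-map mean:

$$P(\text{event}) = \mathrm{logit}^{-1}\!\big(\beta_0 +
\beta_1(\bar D_{\text{region}} - \bar D_{\text{map}} - d_{\mathrm{ref}})
 + \gamma\, b\big)$$

with b the baseline indicator. Driving the outcome by the *excess*
rather than the raw regional mean is deliberate: prescriptions vary
between patients, so a raw-mean driver correlates *every* voxel with
the outcome through the shared dose scale, and the significance map
degenerates to the whole surface. The excess driver removes that global
factor, leaving localized dose-response while the smooth falloff still
produces realistically broad significant regions. Defaults
(d_ref = 43 Gy, β₁ = 0.06 per Gy, β₀ = logit 0.4, γ = 1) were
calibrated so that the uncorrected event rate is ≈ 40-50%, the
planted-region peak t statistic sits comfortably above the permutation
threshold across seeds, and a zero-effect cohort yields a clean map.
Given an event, the maximum follow-up grade is drawn from a severity
distribution (65/25/10% for grades 1/2/3) and placed at 12 or 24
months; the maximum follow-up grade is ≥ 1 exactly when the event was
drawn, so the generator and the dichotomizer agree by construction.

### Reproducibility

Every patient and stage draws from its own seed,
`patient_seed(seed, index, stage)`, a simple congruential mix whose
output always fits `set.seed()`. Regenerating any patient, or the
toxicity of an existing cohort under a different effect size, never
disturbs other streams.

### Known limits

* Organ shapes are star-convex; pathological geometries (severely
  folded rectal walls, diverticula) are out of scope.
* The dose model has no couch/beam geometry; dose anisotropy beyond
  the target anchoring and cosine modulation is absent.
* Grades are drawn independently across endpoints given dose; real
  endpoints are correlated through patient-level frailty.
* The planted region is rectangular in map coordinates — convenient
  for overlap accounting, anatomically arbitrary.

## 6. Problem sizes and runtime

Generating a 400-patient bladder cohort takes ≈ 20 s (dominated by
surface bisection); 1000 permutations of a 400 × 8190 stack ≈ 8 s; the
complete null-calibration study (400 cohorts × 1000 permutations)
≈ 2 minutes. The full test suite, including the calibration and
recovery studies at full scale, runs in well under half an hour on one
CPU.

## 7. Worked example

```{r example}
library(drmap)

spec <- cohort_spec(n_patients = 120, organ = "bladder", seed = 42)
cohort <- generate_cohort(spec)

cfg <- run_config(cohort, statistic = "welch", n_iterations = 1000,
                  tails = "upper", seed = 42)
result <- run_drm_analysis(cfg)
print(result)

# where is the significant subregion?
key <- "urinary_incontinence.uncorrected"
mean_dose <- matrix(colMeans(cohort$stack$X), 91, 90)
plot_drm(result$analyses[[key]], mean_dose = mean_dose, organ = "bladder")

# agreement between the two labelling rules
result$comparison
```
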