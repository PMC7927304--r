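---
title: "Interoception and white-matter microstructure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interoception and white-matter microstructure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intertract)
```

This vignette is the package's account of its science: the scoring models,
the voxel-based statistics, the streamline machinery, the lesion-mapping
procedure, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## The analysis problem

Functional neurological disorder (FND) research has linked disturbed
interoception — the sensing of internal bodily signals — to alterations in
white-matter pathways connecting interoceptive and multimodal-integration
cortex. The analysis implemented here relates three per-subject behavioral
quantities to diffusion-tensor fractional anisotropy (FA):

* **Heartbeat-tracking accuracy (HTT)** — objective cardiac interoception,
* **Body-awareness score (BPQ-awareness)** — self-reported sensitivity to
  internal sensations, and
* **Interoceptive trait prediction error (ITPE)** — the z-scored discrepancy
  between the two,

through four stages: behavioral scoring and group statistics; voxel-based FA
analysis (VBA) with Monte-Carlo cluster-wise correction; projection of the
surviving clusters ("blobs") onto streamline bundles via a probabilistic
atlas; and white-matter-to-gray-matter network lesion mapping, which asks
which gray-matter regions' emanating tracts traverse the blob.

Because the study's patient data are not publicly deposited, the package
ships a first-class synthetic-data module that reproduces the *structure* of
the inputs — a two-subtype patient cohort with covariates, FA volumes with
localized embedded effects, tubular fiber bundles with known endpoint
regions, and 12-window heartbeat-tracking trials — with seeded ground truth
against which every stage is validated.

## Behavioral scoring

### Heartbeat-tracking accuracy

For counting windows indexed by trials with `rec` recorded R-peaks and
`count` reported beats,

$$\mathrm{HTT} = \frac{1}{n}\sum_{\text{trials}}
  \left(1 - \frac{|rec - count|}{rec}\right).$$

The formula is applied literally: scores above-estimating by more than a
factor of two go negative and are not clamped, and when a subject has fewer
than 12 usable windows the mean is over the usable trials (the reference
procedure does not state the denominator for that case; dividing by the
usable count keeps the score an unbiased mean of per-trial accuracies).

```{r}
htt_score(data.frame(rec = c(20, 25), count = c(18, 30)))
```

### ITPE

HTT and BPQ-awareness are converted to z-scores and subtracted,
`itpe = z(bpq) - z(htt)`; positive values mean a subject reports more bodily
awareness than their objective accuracy supports. Two conventions were
open:

* **z-scoring sample.** The reference analysis does not state whether
  z-scores were computed over the combined sample or within groups. The
  default is the combined sample of all participants with usable ECG
  (patients and controls analyzed together share one scale); per-group
  scoring is available via `itpe_scores(..., scope = "group")`.
* **SD denominator.** The sample (n−1) standard deviation is used, the
  convention under which the worked three-subject example
  (`bpq = 80, 100, 120`, `htt = 0.9, 0.7, 0.5` giving `itpe = -2, 0, 2`)
  comes out exact.

Within the z-scoring sample ITPE sums to zero by construction; the test
suite asserts this to 1e-10.

### Group statistics

Group comparisons use t tests / one-way ANOVA with a variance-homogeneity
gate: when the Brown–Forsythe test (the median-centered Levene variant, the
more robust of the two common forms) rejects at p < .05, the Welch-adjusted
statistic replaces the classical one. The reference procedure names the
gate but not the variant or threshold; both are package choices exposed as
arguments. Accuracy and ITPE group effects are additionally assessed by
ANCOVA controlling for BMI (`outcome ~ bmi + group`, group tested after the
covariate), and p values are Benjamini–Hochberg adjusted across the tested
scores.

## Voxel-based analysis

FA volumes are smoothed with an isotropic Gaussian kernel of **sigma 1 mm**,
restricted to the white-matter mask with kernel renormalization at the mask
boundary (`conv(vol·mask)/conv(mask)`), so constants are preserved exactly
and no signal bleeds across the mask edge. Per voxel, an ordinary
least-squares GLM is fitted with intercept, the effect of interest (group
indicator or behavioral score) and covariates — age, sex (0/1), head motion,
depression and trait anxiety, plus BMI for within-group analyses. Covariates
are mean-centered; this leaves contrast t values unchanged (the tests assert
invariance to affine covariate rescaling) and improves conditioning.

### Cluster-wise Monte-Carlo correction

The t map is thresholded two-sided at the voxel-level cluster-forming
probability `cft_p` (default **p = .001**, a standard conservative choice;
the reference procedure does not state its threshold), connected components
are labeled (**26-connectivity** default; 6/18 available), and each observed
cluster receives

$$p_{\mathrm{corr}} = \frac{1 + \#\{\text{null max extent} \ge
  \text{observed extent}\}}{n_{\mathrm{iter}} + 1},$$

the +1 permutation-style estimator that avoids zero p values. Null fields
are Gaussian white noise smoothed to the smoothness of the GLM residuals,
standardized within the mask, and thresholded at the matching normal
quantile; the reference configuration is **10,000 iterations** with cluster
retention at corrected **p < .05**.

Two numerical points matter here:

* **Smoothness round trip.** Residual smoothness is estimated per axis from
  the variance of first differences of the residuals,
  `FWHM = sqrt(8 log 2) dx / sqrt(2 var(diff)/var)`. On a discrete grid this
  continuous-field formula is a few percent biased for the generating kernel,
  so the null generator does not invert it through `FWHM/2.355`; it inverts
  the *same discrete measurement* (Gaussian ACF of smoothed white noise),
  making the null fields' measured smoothness equal the residuals' by
  construction. Without this the null clusters are systematically larger and
  the correction over-conservative.
* **Gaussian approximation to the t field.** Simulating Gaussian rather than
  t-distributed null fields is the classic design of this correction family.
  At low degrees of freedom the t field is rougher than its Gaussian
  numerator and the correction errs conservative (fewer false positives than
  nominal). The calibration test therefore runs at the degrees of freedom
  scale of the actual cohort analyses (n = 60, two groups of 30, df = 58),
  where the family-wise error at alpha = .05 falls within the 99% binomial
  confidence band of the nominal rate.

### Effect sizes

Two conventions, chosen to reproduce the published values exactly:

* two-sample contrasts: `d = |t| sqrt(1/n1 + 1/n2)` — with t = −5.76 and
  groups of 21 and 38 this gives 1.566;
* continuous (within-group correlation) contrasts: `d = |t|/sqrt(n)` — this
  is the convention under which every published within-group effect size
  (0.97, 0.99, 0.89, 0.90, 1.03, 0.96, 0.73 at n = 33) is recovered to two
  decimals, and it is preferred here over `2t/sqrt(df)`, which does not
  reproduce them.

## Streamline machinery

Full probabilistic tractography (crossing-fiber modeling plus sampling-based
propagation) is out of scope; a **deterministic tracker on synthetic
orientation fields** stands in. It propagates bidirectionally from each seed
along the voxel-wise orientation, with antipodal-aware sign continuation
(orientations are axial: v ≡ −v), choosing at each step the available
population (primary or recorded crossing direction) most aligned with the
incoming direction, and terminating at mask exit, null orientation, or a
per-step turning angle above `max_angle_deg`.

All voxel membership questions use one convention, stated once and enforced
everywhere: world coordinates are RAS+ mm, voxel indices are 0-based, voxel
boxes are half-open around the voxel center, and a streamline's voxels are
found by exact segment–plane crossing enumeration (no sampling), including
the voxels containing the polyline's own endpoints.

### The three filters

* **Visitation probability (< 0.1%).** The per-voxel visitation map is the
  fraction of streamlines intersecting the voxel (multiple crossings count
  once). A fiber is eliminated when it traverses any voxel visited by fewer
  than 0.1% of fibers — the more explicit of the two published phrasings of
  the rule, and the interpretation adopted here. Note the rule only binds
  for sets of more than 1,000 fibers; below that every fiber supports its
  own voxels at ≥ 0.1%.
* **Curvature (> 70).** The published threshold "curvature > 70%" is read as
  a **70-degree maximum inter-segment turning angle** — percent curvature is
  not a standard quantity, and a degree threshold is what the tracking
  literature uses. Streamlines with fewer than three points have zero
  curvature.
* **Crossing fibers (5% within ±15°).** Per voxel, the local travel
  directions of all traversing streamlines are collected with antipodal
  symmetry; the modal direction maximizes the fraction of directions within
  15° of itself. A fiber is flagged where it deviates more than 15° from the
  mode *and* fewer than 5% of the voxel's directions lie within 15° of its
  own direction; flagged fibers are removed whole (the rule removes
  "fibers", not segments). The default histogram is a continuous
  spherical-cap mass around each observed direction, avoiding bin-edge
  artifacts; a binned variant (`method = "binned"`) is provided for
  comparison.

Filters always return subsets, and the pipeline applies them in the
published order (probability and curvature, then the crossing rule). They
are not interchangeable — the tests construct a set where a parallel-but-
offset stray passes the direction histogram but fails the probability floor.

### Bundles, atlas, projection

Bundle selection is query-based: a streamline belongs to a bundle when its
endpoints lie in the query's start/end label sets (orientation-free), it
visits every waypoint set, and no exclusion label. The group atlas is built
from control subjects only: per voxel, the fraction of controls with at
least one bundle streamline there. VBA blobs are projected onto bundles with
at least **25% membership probability**; the published rule is ambiguous
between a per-voxel and a bundle-level threshold, and the per-voxel reading
is implemented — each blob voxel may belong to several bundles, and the
report ranks bundles by the fraction of blob voxels they cover.

## Network lesion mapping

For each parcellation region, **100 fibers** are tracked from seeds sampled
uniformly within the region (with replacement when the region is smaller);
fibers with visitation probability below **1%** within the region's own set
are eliminated; the overlap percent is 100 × (blob voxels reached by a
surviving fiber)/(blob voxels). Percentages are averaged **across subjects**
per region — the only replicate dimension available per region–blob pair;
the published description leaves the averaging axis implicit. Regions are
displayed when the mean strictly exceeds **10%** (a mean of exactly 10 is
not displayed, matching the "> 10%" phrasing).

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed, not
tuning knobs.

**Cohort.** 21 + 17 patients and 38 controls; sex ratios from the
demographics table (19F/2M, 13F/4M, 32F/6M); ages, BMI, depression (BDI)
and trait anxiety (STAI-trait) drawn from the published group means and SDs;
head motion is an invented nuisance summary (0.45 ± 0.15 mm patients,
0.40 ± 0.12 mm controls). True interoceptive accuracy follows the published
score distributions (patients 0.63 ± 0.26, controls 0.70 ± 0.21) truncated
to [0, 1]. Exactly 3 + 2 patient and 4 control ECGs are flagged unusable by
default, reproducing the exclusion bookkeeping (33 patients, 34 controls in
accuracy analyses); a Bernoulli dropout is available instead. The published
text and per-patient table disagree on two details (movement-subtype sex
split 12F/5M vs 13F/4M; seizure-subtype mean age 23.0 ± 2.8 vs table rows
implying ≈ 30): the packaged fixture follows the table rows verbatim, the
generator follows the stated summary distributions, and neither resolves the
discrepancy.

**Trials.** Heart rate is uniform on [55, 95] bpm with a fixed-rate beat
train (no heart-rate variability) — the simplest model sufficient for
scoring tests. Windows use the stated lengths {15, 18, 21, 24, 27, 30} s,
each twice, in random order. Reports follow
`count = round(rec (a + e))`, `e ~ N(0, 0.1)`, truncated at zero — no report
model is published; this one makes the expected relative counting error
≈ 1 − a, so mean recovered accuracy converges to the latent accuracy (the
tests verify the small folded-normal correction from the model itself).
Awareness item responses are constructed deterministically from a latent
total (correlated 0.3 with true accuracy); item-level response styles are
not modeled.

**Phantom.** Two orthogonal straight tubes (radius 2.2 mm) crossing at the
center of a 36 × 36 × 12 mm grid at 1 mm isotropic resolution, with endpoint
label regions at the tube ends. The group effect (**−0.15 FA** in patients,
the magnitude the recovery power analysis is built around) sits on one
bundle; the accuracy correlate (**0.5 FA per accuracy unit**, centered at
accuracy 0.65) on the other; FA baseline 0.5 in tubes over a 0.1 background,
small age/sex nuisance effects over the mask, Gaussian noise **SD 0.08**
(realistic FA measurement noise), clipped to [0, 1]. The phantom's
axis-aligned affine plays the role of template space — registration is out
of scope, so all volumes share the space by construction.

**What passing tests do not show.** The generator has no DWI signal, tensor
fit, registration error, heart-rate variability, raw ECG artifacts, real
parcellation geometry, or realistic fiber dispersion; recovery results on
phantoms demonstrate the correctness of the scoring, statistics, filtering
and mapping machinery under known ground truth, not performance on acquired
diffusion data.

## Reproducibility and problem sizes

All randomness flows from a single configuration seed through per-stage
derived sub-seeds; two runs with the same configuration produce
byte-identical tables. Every pipeline default equals the reference value
(1 mm sigma; 10,000 iterations; 0.1%; 70°; 5%; ±15°; 25%; 100 fibers; 1%;
10%).

The simulation-heavy checks run at deliberately scaled sizes chosen by the
package: the family-wise-error calibration uses a 32³ solid mask, 1,000-
iteration null, 500 replicate maps at n = 60; end-to-end recovery uses 20
pipeline replicates with 200-iteration nulls, 60 seeds per bundle, 5 atlas
controls and 3 lesion-map subjects at 50 fibers per region. The acceptance
script reruns the same computations at comparable sizes.

## Known limitations

* The deterministic tracker is a stand-in: it does not sample orientation
  uncertainty, so per-subject tract variability in synthetic runs comes only
  from seed jitter.
* The Gaussian null underlying the cluster correction is mildly conservative
  at low degrees of freedom (see above).
* The crossing-fiber rule removes whole fibers; partial-voluming of genuine
  minor populations at bundle edges can therefore trim true fibers — the
  recovery tests bound this at the 5% level the rule implies.
* TRK reading supports the plain v2 layout written by this package (no
  per-point scalars or properties).
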