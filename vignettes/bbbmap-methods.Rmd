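---
title: "Rank-based voxel mapping of edema and blood-brain-barrier dysfunction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based voxel mapping of edema and blood-brain-barrier dysfunction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbmap)
```

## The problem

Contrast-enhanced MRI is the standard readout for two linked quantities in
preclinical neuro-oncology and brain-stimulation studies: *edema load*,
visible as hyper-intense signal on T2-weighted scans, and *blood-brain
barrier dysfunction* (BBBD), visible as signal enhancement on T1-weighted
scans acquired after administration of a gadolinium contrast agent that
only accumulates where the barrier leaks. Both are usually reported as
**relative volumes**: the number of classified voxels divided by the number
of brain voxels, in percent.

Absolute MRI intensities are arbitrary and vary between sessions, coils and
subjects, so thresholding raw intensities is fragile. `bbbmap` instead
classifies each voxel by a *nonparametric rank comparison* of its local
signal distribution against a within-scan reference region, which makes the
maps invariant to any positive rescaling of the data — a property the test
suite verifies exactly.

## The detection model

For every brain voxel the **environmental sample** is the set of
intensities in its in-plane 3&times;3 neighborhood, intersected with the
brain mask (1-9 values; border voxels use truncated neighborhoods, because
padding would invent data). The neighborhood is two-dimensional because
multi-slice rodent MRI is strongly anisotropic — through-plane spacing is
several times the in-plane spacing — so in-plane neighbors are the
homogeneous ones; a 3-D neighborhood mode is deliberately not offered.

**T2w hyper-intensity.** A voxel is classified hyper-intense when all three
hold:

* (a) a one-sided Mann-Whitney test rejects, at level $\alpha$, the null
  that its environmental sample and the **contralateral reference sample**
  (all brain voxels of the hemisphere opposite the lesioned/stimulated
  side) are exchangeable, in the direction *environment above reference*;
* (b) its own intensity exceeds the reference mean;
* (c) its environmental mean exceeds the reference mean.

**BBBD.** A voxel is classified BBBD-positive when:

* (a) its post-contrast environmental sample ranks above its pre-contrast
  environmental sample at the same location (one-sided Mann-Whitney at
  $\alpha$, exact null distribution — both samples have at most nine
  values);
* (b) its post-contrast intensity exceeds its pre-contrast intensity;
* (c) its post-contrast environmental mean exceeds the mean **temporal
  muscle** reference signal.

The muscle reference in (c) is taken from the *post-contrast* scan. The
agent is administered intramuscularly and muscle has no barrier, so muscle
enhancement tracks systemic agent levels; referencing the post-contrast
muscle signal is what lets condition (c) cancel *global* enhancement that
affects brain and muscle alike, a property checked explicitly by the
specificity suite. A pre-contrast muscle reference is available as an
option but weakens exactly that control.

The pre/post comparison presumes the two T1w scans are aligned; the
pipeline refuses unregistered input unless explicitly overridden.

### The voxel-level $\alpha$

$\alpha$ is the single most consequential tuning parameter. No multiplicity
correction is applied — the classification is per-voxel by design, and the
mean conditions (b)/(c) were intended to suppress chance positives. In
practice (b) and (c) are strongly positively correlated with the rank
condition (a), because all three are driven by the same local noise
average, so the chance-positive floor is close to $0.8\alpha$ of the brain
volume. At $\alpha = 0.01$ on a ~50,000-voxel brain that floor is ~0.8% of
brain — negligible against large lesions but a +40% bias when quantifying a
lesion occupying 2% of brain. The package therefore defaults to
$\alpha = 0.001$, where the floor (~0.05%) is far below the smallest
lesion loads of interest while interior lesion voxels at the effect sizes
the phantom emulates (4 noise-SD) are still detected with near-certainty.
`alpha` is exposed on every detector and in the pipeline config for
sensitivity analysis; the false-positive suite additionally verifies the
$\alpha = 0.01$ setting stays under its ceiling.

### Reference handling

The rank test uses the full reference sample by default: it is exactly
deterministic and the vectorized scan of a fixed sorted reference makes the
cost independent of reference size. Seeded subsampling
(`ref_subsample`/`ref_seed`) is available when a bounded test sample is
wanted; reference *means* for conditions (b)/(c) are always computed on the
full reference.

## The Mann-Whitney machinery

The rank test is implemented in-package, in two routes:

* **Exact**: the null distribution of the rank-sum statistic $U$ (midranks
  for ties) is computed by a subset-sum dynamic program over the observed
  doubled-midrank multiset. Doubling makes every midrank an exact integer,
  so exact-mode p values are bit-identical to full enumeration under
  arbitrary tie patterns. Used whenever $n_A n_B \le$ `exact_limit`
  (default 400), which covers the per-voxel pre/post comparison (at most
  9&times;9) and typical group sizes.
* **Normal approximation**: tie-corrected variance with a 0.5 continuity
  correction, used for the voxel-vs-reference comparison where the
  reference has thousands of values. The per-voxel tie correction is exact
  and vectorized: an environmental value matching a reference tie group of
  size $r$ changes $\sum (t^3-t)$ by $3r^2+3r$; the rare voxels whose
  environmental sample contains exact internal duplicates fall back to the
  scalar path.

A brute-force oracle (`mwu_oracle`, full enumeration of all
$\binom{N}{n_A}$ label assignments, $N \le 12$) is shipped as a first-class
function and the exact route is verified against it over hundreds of tied
integer samples; the two share no code path beyond midrank computation.
Two-sided p values are twice the smaller tail, capped at 1 — the midrank
null is symmetric — and "all values identical" returns p = 1 by convention.

## Brain segmentation

Brain extraction follows the histogram-band rule: an accepted band is
estimated from a brain seed region and a rejected band from a peripheral
seed region; brain voxels are those inside the accepted and outside the
rejected band. Design choices:

* Seeds default to the central block (one quarter of each grid extent) and
  a two-voxel border shell; explicit seed masks can be supplied.
* Bands are the central 95% (2.5th-97.5th percentile) of each seed's
  intensities — percentile bands are robust and scale-equivariant, making
  segmentation invariant to affine intensity rescaling.
* Cleanup keeps the largest 6-connected component and fills interior holes
  (the band criterion excludes ~5% of genuine brain voxels by
  construction; almost all are isolated interior holes). The pre-cleanup
  mask is returned as `band_mask` so the band property remains checkable.
* A flat or unimodal image, where the bands cannot be separated or select
  only a sliver (under `min_mask_fraction`, default 1% of the grid),
  raises a `bbbmap_segmentation_failure` error — never an empty mask.

## Registration

Within-session motion between the pre- and post-contrast T1w scans is
small, so the registration model is a translation (an optional in-plane
rotation grid is available behind `mode = "rigid"`); the optimum is found
by exhaustive integer-shift search of normalized cross-correlation inside a
configurable window, which is deterministic and cannot be trapped in local
optima. Subvoxel refinement fits a parabola per axis through the three
integer-shift scores around the peak. Refinement deliberately does *not*
optimize interpolated NCC directly: linear resampling smooths noise, so a
fractionally resampled volume correlates better with anything smooth than
the unresampled one does, which biases such an optimizer away from integer
shifts even on axes with no true displacement; fitting the unbiased
integer-shift scores avoids this, and the test suite holds the recovered
fractional shifts to a quarter voxel. An optimum on the window
boundary is flagged in the returned transform. Volumes are resampled with
separable linear interpolation; masks with nearest-neighbor.

## Endpoints

Group results are summarized as median and interquartile range (quantile
type 7, linear interpolation between order statistics, switchable), and
compared with the package's unpaired Mann-Whitney test. Survival uses the
Kaplan-Meier product-limit estimator (curves from the survival package,
events before censorings at tied times) with the median defined as the
earliest time the estimate reaches 0.5 or below, undefined when the curve
never does; group differences use the log-rank (Mantel-Cox) chi-squared
with $k-1$ degrees of freedom. Day-over-day comparisons within animals are
treated as unpaired, matching the test actually named for them.

## The phantom

Because no animal MRI data accompany the method, every claim is validated
on a synthetic phantom whose *statistical* structure matches what the
detector assumes, with exact ground truth:

* an axis-aligned brain ellipsoid (default 30% of the grid) on a dark
  background, with a peripheral muscle shell — the simplest geometry with a
  well-defined contralateral mirror;
* a T2w-hyper-intense lesion and a post-contrast-enhancing leakage region,
  realized as the $k$ nearest brain voxels (physical distance,
  deterministic tie-break) around centers in the right hemisphere, so the
  true fractions are exact integer ratios; by default the two regions are
  disjoint (leakage is drawn from non-lesion voxels), with overlap behind
  an explicit flag;
* contrasts parameterized in units of the noise SD, so detection power is
  controlled directly: T2w brain tissue sits 5 SD above background, muscle
  2.5 SD; on T1w, muscle (6 SD) sits slightly above parenchyma (5 SD),
  reflecting that the intramuscularly dosed, barrier-free muscle is meant
  to be a conservative reference for systemic enhancement;
* additive gaussian noise by default — it keeps analytic checks simple —
  with Rician magnitude noise (the physical MRI model) as an option whose
  zero-signal background is verified against Rayleigh moments;
* an optional, possibly fractional, inter-scan translation of the
  post-contrast scan, applied to the clean signal before its independent
  noise draw, to exercise (sub)voxel registration.

Identical seed and parameters give bit-identical output; region geometry
does not depend on the noise seed.

The default grid is 96&times;96&times;18 voxels at 0.2&times;0.2&times;1 mm
— a rodent-like field of view with realistic through-plane anisotropy, and
the standing problem size for all simulation suites: detector recovery runs
50 seeds per lesion fraction, false-positive and specificity suites 50
seeds, segmentation 20 seeds, the contrast-monotonicity series 9 seeds per
level, and the log-rank permutation null 10,000 permutations of 30
subjects. The built-in demo cohort is two groups of eight subjects on the
same grid.

What the phantom does **not** emulate: anatomical brain shape, partial
volume and bias fields, pharmacokinetic (Tofts-style) enhancement dynamics,
scanner artifacts beyond noise and rigid shift, or spatially correlated
noise. Passing the suites therefore demonstrates that the implementation
realizes the stated decision rule with calibrated error control under the
assumed statistical structure — not that the rule is robust to artifacts
real scans may contain. The demo's survival endpoint is likewise synthetic
(seeded Weibull times with administrative censoring) and exercises the
machinery, not biology.

## Worked example

```{r demo, eval = FALSE}
library(bbbmap)
ph <- generate_phantom(phantom_params(seed = 1))          # truth: 10% lesion, 8% leakage
seg <- segment_brain(ph$scans$t2w)
t2 <- detect_t2w_hyperintensity(ph$scans$t2w, seg$brain_mask,
                                mirror_reference_mask(seg$brain_mask, "right"))
bb <- detect_bbbd(ph$scans$t1_pre, ph$scans$t1_post,
                  seg$brain_mask, ph$scans$muscle_mask)
c(t2w = t2$relative_volume, bbbd = bb$relative_volume)

res <- run_pipeline(default_demo_config(seed = 1), out_dir = "demo_out")
print(res)
```

## Known limitations

* The contralateral reference presumes unilateral pathology; bilateral
  disease contaminates the reference and biases the T2w map downward. The
  degenerate case (no usable contralateral voxels) errors rather than
  guessing.
* Registration is translation-first; rotation support is a coarse in-plane
  grid, and deformable motion is out of scope.
* The per-voxel error rate is controlled marginally, not family-wise; maps
  should be read as quantification, not as voxel-wise inference corrected
  for multiplicity.
* Heavily quantized intensities route many voxels through the scalar tie
  fallback, which is exact but slow relative to the vectorized continuous
  path.
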