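# bbbmap

Voxel-wise, rank-based quantification of brain edema and blood-brain
barrier dysfunction (BBBD) from structural and contrast-enhanced MRI, for
preclinical imaging studies that report lesion load and barrier leakage as
*relative brain volumes* and compare them across treatment groups.

## What it computes

For every brain voxel, the **environmental signal** is the set of
intensities in the in-plane 3×3 neighborhood around it (restricted to the
brain mask). `bbbmap` produces two binary maps:

* **T2w hyper-intensity (edema)** — voxel positive iff its environmental
  sample ranks above a contralateral-hemisphere reference sample by a
  one-sided Mann-Whitney U test at level α, *and* both its own intensity
  and its environmental mean exceed the reference mean.
* **BBBD** — voxel positive iff its post-gadolinium environmental sample
  ranks above the pre-contrast sample at the same location (one-sided MWU,
  exact null), *and* post > pre at the voxel itself, *and* the
  post-contrast environmental mean exceeds the mean temporal-muscle
  reference signal (which cancels systemic enhancement).

Each map is summarized as a relative volume,
`# positive voxels / # brain voxels`, reported as a percentage. Around this
core the package provides histogram-band brain segmentation, rigid
registration of the post-contrast scan (exhaustive NCC search with subvoxel
refinement), a self-contained exact/approximate Mann-Whitney U
implementation verified against a brute-force enumeration oracle, group
endpoint statistics (median/IQR, rank comparisons, Kaplan-Meier survival
with log-rank Mantel-Cox tests), NIfTI I/O, and a synthetic phantom
generator with exact ground-truth masks that makes the whole pipeline
testable without animal data.

## Worked example

```r
library(bbbmap)

ph  <- generate_phantom(phantom_params(seed = 1))   # truth: 10% lesion, 8% leakage
seg <- segment_brain(ph$scans$t2w)
t2  <- detect_t2w_hyperintensity(ph$scans$t2w, seg$brain_mask,
                                 mirror_reference_mask(seg$brain_mask, "right"))
bb  <- detect_bbbd(ph$scans$t1_pre, ph$scans$t1_post,
                   seg$brain_mask, ph$scans$muscle_mask)
print(t2)
#> <detection_map> t2w_hyper: 4796 voxels, relative volume 0.1012 (10.12%), alpha 0.001
print(bb)
#> <detection_map> bbbd: 3437 voxels, relative volume 0.0726 (7.26%), alpha 0.001
```

The phantom was generated with a lesion occupying 10% of the brain and a
leakage region occupying 8%; the detected relative volumes (10.12% and
7.26%, using the *segmented* brain mask and its mirrored contralateral
reference) recover those loads. The full pipeline — cohort generation,
registration, segmentation, both detectors, group statistics, survival —
runs from one config:

```r
res <- run_pipeline(default_demo_config(seed = 1), out_dir = "demo_out")
print(res)   # per-group median (IQR) relative volumes, log-rank p, ...
```

which writes `volumes.csv`, `survival.csv`, `report.json`, per-subject map
overlays (NIfTI) and a reproducibility manifest. A thin CLI wraps the same
functions: `inst/cli/bbbmap {phantom|detect|endpoints|run} --seed N --out dir/`.

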