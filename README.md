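# octava

Automated vascular analysis of en-face macular OCTA angiograms, and visual
acuity estimation from the resulting biomarkers.

## The problem

Optical coherence tomography angiography (OCTA) produces en-face maps of
retinal blood flow without dye injection. In retinal vein occlusion (RVO) —
the second most common retinal vascular disease — two vascular biomarkers
carry prognostic weight: the area of the **foveal avascular zone (FAZ)**, the
capillary-free region at the center of the fovea, and the **vascular density
(VD)** of the superficial and deep capillary plexuses (SCP, DCP) around it.
Measuring them by hand is slow and subjective, and commercial device software
offers no quantitative readout for the deep plexus at all. `octava` is a
fully automatic pipeline for clinicians and imaging researchers: given the
four en-face scans of a visit (SCP/DCP at 3×3 and 6×6 mm), it segments the
vasculature, measures the FAZ, quantifies density per ETDRS grid zone in both
plexuses, and estimates the patient's decimal best-corrected visual acuity
(BCVA) from those numbers.

## The method

1. **Vessel segmentation** — Otsu's criterion on the 256-bin gray histogram:
   the threshold *t* maximizes the between-class variance σ²ᵦ(t)
   (equivalently the ratio Q(t) = σ²ᵦ(t)/σ²_w(t), since
   σ²ᵦ + σ²_w = σ²_total). Pixels strictly above *t* are vessel.
2. **Skeletonization** — classic two-subiteration parallel thinning
   (Zhang–Suen) reduces the vessel mask to a one-pixel-wide skeleton,
   preserving 8-connectivity.
3. **FAZ segmentation** — staged: Gaussian smoothing, vascular edge map
   (Otsu mask + morphological closing), candidate avascular components,
   morphological false-positive filtering (area, centrality, compactness),
   final selection of the most central FAZ-shaped region, boundary
   refinement on the unsmoothed vessel mask, hole filling, area in mm².
4. **Zonal density** — the ETDRS grid (1 mm foveal disk, 3 mm outer ring
   split into upper/nasal/temporal/lower quadrants, nasal–temporal mirrored
   between OD and OS) is centered on the FAZ; each zone's density is
   `Dens = Σ skeleton pixels / zone pixel count`, a fraction in [0, 1].
5. **VA estimation** — the 21 biomarkers (FAZ area + 4 scans × 5 zones) feed
   an epsilon support-vector regression (linear kernel, z-scored features,
   solved exactly as a QP) evaluated with seeded 5-fold cross-validation:
   Pearson r, p-value and MSE on the decimal VA scale, plus the optimistic
   all-data train MSE for comparison. `decimal_to_logmar()` converts
   decimal VA to −log₁₀(VA).

No public OCTA dataset accompanies the method, so the package ships a seeded
synthetic generator: jittered capillary lattices with a perifoveal arcade
ring bounding an avascular disk of known area, per-zone capillary dropout,
intensity noise, and cohorts whose VA follows a known linear law over the
vascular ground truth. Every stage is validated against that ground truth.

## Worked example

```r
library(octava)

# a synthetic 3x3 mm SCP angiogram with a 0.30 mm FAZ
gen <- generate_vessel_image(vessel_fixture_spec(
  size_px = 320, extent_mm = 3, faz_radius_mm = 0.30, seed = 5
))
img <- gen$image

faz <- detect_faz(img)
faz
#> <faz_region> area 0.2837 mm2, centroid (160.0, 160.0), 531 candidates considered
pi * 0.30^2   # analytic truth
#> [1] 0.2827433

skel <- skeletonize(binarize(img, otsu_threshold(img)$threshold))
zones <- build_etdrs_masks(dim(img$pixels), faz$centroid_px,
                           scale_mm_per_px(img), img$laterality)
zonal_density(skel, zones, img$plexus, img$extent_mm)
#> <density_profile> SCP 3 mm
#>   foveal    0.1129
#>   upper     0.1607
#>   nasal     0.1577
#>   temporal  0.1596
#>   lower     0.1569
#>   global    0.1504
```

The FAZ area lands within ~1% of the rendered truth; the foveal zone's
density is depressed because the avascular disk occupies most of it. A whole
cohort runs end to end with:

```r
csv <- simulate_cohort("scratch/demo", n_visits = 40, size_px = 128, seed = 1)
report <- run_pipeline(run_config(csv, "scratch/demo/out", seed = 1))
report$metrics[c("pearson_r", "mse_decimal", "train_mse")]
#> $pearson_r    [1] 0.8413857
#> $mse_decimal  [1] 0.002178366
#> $train_mse    [1] 0.001462611
```

i.e. the estimator recovers VA from re-measured images with r ≈ 0.84 on
held-out folds, and the in-sample error is (as always) flattering. The same
pipeline is scriptable from a shell via the installed launcher:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "octava", package = "octava"))')" \
  run --cohort scratch/demo/cohort.csv --out scratch/demo/out --seed 1
```

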