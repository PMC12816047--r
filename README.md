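# spatialtime

Region-referenced gradient analysis for array-based spatial
transcriptomics, built for studies of focal lesions such as
trauma-induced heterotopic ossification (HO), where the question is not
*which* genes or cell types are present but *where they sit relative to
a landmark* — here, the early bone condensation ("anlagen") that forms
at the injury site. The package also quantifies collagen-fibril
alignment in grayscale microscopy images (second harmonic generation of
tendon and lesion matrix) and bundles the group-comparison statistics
such studies report.

It is aimed at researchers who have spot-level data (coordinates,
counts, and label-transfer prediction scores from an upstream pipeline)
plus a manually marked region, and want a reproducible distance-gradient
analysis without a hand-rolled notebook.

## The method

**SpatialTime.** Given spot centers and a binary raster of the marked
region, each spot receives its minimum Euclidean distance to the
region's positive pixels,

d_i = min over region pixels p of ‖x_i − p‖,

then distances are min–max scaled to the SpatialTime axis
s_i = (d_i − min d) / (max d − min d) ∈ [0, 1], with 0 at the region and
1 farthest from it. Spots inside the region score 0 by default; a
`signed` option gives them the negative distance to the region's
complement, so the region border sits at a positive axis position and
profiles extend across it.

**Classification and profiles.** Spots are called cell-type positive
when their prediction score is ≥ 0.6. Any per-spot quantity
(log-normalized expression, a prediction score) is averaged in
left-closed SpatialTime bins of width 0.01 — 100 bins with per-bin n,
mean, and standard error (sd/√n) — and smoothed with a centered moving
average over the nearest non-empty bins. From the smoothed curve the
package extracts the peak location, a spot-level Spearman trend test,
a direction label (increasing / decreasing / peaked / flat), and the
crossing points of two profiles after per-profile min–max scaling.

**Fibril anisotropy.** For each region of interest in a grayscale image
the package averages the outer product t tᵀ of the per-pixel unit
tangent (perpendicular to the intensity gradient) into a trace-1 nematic
tensor; the anisotropy score AU = λ₁ − λ₂ of its eigenvalues is 0 for
isotropic and 1 for perfectly aligned fibers, and the leading
eigenvector gives the mean orientation in (−90°, 90°].

**Statistics.** Two-group comparisons run an automatic selector:
Shapiro–Wilk normality per group (failures route to the two-sided
Mann–Whitney U test), then a median-centered Levene test choosing
between Student's and Welch's t. Multi-group data use ordinary one-way
ANOVA. All tests are two-sided at α = 0.05 and the full decision trail
is recorded.

Synthetic-data generators (spot lattices with a disk region,
gradient-structured negative-binomial counts, prediction-score fields,
fibril images with known orientation concentration) make every stage
testable end to end with known ground truth.

## Worked example

```r
library(spatialtime)

scene <- simulate_scene(seed = 1)    # 2000-spot lattice, disk anlagen
scene$st
#> <spatialtime_scores> 2000 spots, raw distance -60.01..334.59 px (signed)
#>     spot_id raw_distance spatialtime
#> 1 spot_0001     190.0000   0.6335707
#> 2 spot_0002     184.1738   0.6188060
#> ...

classify_spots(scene$table$scores)   # cutoff 0.6, inclusive
#> <spot_labels> 2000 spots, cutoff >= 0.6
#>   macrophage: 342 positive
#>   mpc: 228 positive

norm <- normalize_expression(scene$table)
prof <- smooth_profile(bin_profile(as.numeric(norm["Thbs2", ]),
                                   scene$st$spatialtime))
profile_features(prof)
#> <profile_features> direction: peaked
#>   peak at SpatialTime 0.325 (prominence 0.849)
#>   Spearman rho -0.675, p 2.82e-266
```

The Thbs2-like gene is recovered as *peaked* at SpatialTime 0.325 — the
generator placed its true maximum at 0.30 — with a strong overall
negative trend. The macrophage/MPC score profiles cross just outside
the anlagen border:

```r
pm <- smooth_profile(bin_profile(scene$table$scores$macrophage,
                                 scene$st$spatialtime))
pp <- smooth_profile(bin_profile(scene$table$scores$mpc,
                                 scene$st$spatialtime))
crossing_points(pm, pp)[1]        # 0.159; true border at 0.152
```

Anisotropy of a synthetic fibril image (concentration 10, two ROIs):

```r
f <- generate_fibril_image(192, 192, mean_angle_deg = 20,
                           concentration = 10, seed = 1)
image_anisotropy(f$image, data.frame(roi_id = c("r1", "r2"),
                                     x0 = c(0, 96), y0 = 0,
                                     width = 96, height = 192))
#> <anisotropy_result> 2 ROI(s), image AU = 0.798
#>   roi_id        au orientation_deg n_pixels_used
#> 1     r1 0.7891136        21.77111          7459
#> 2     r2 0.8072201        21.42230          6970
```

AU ≈ 0.80 against a sampled ground-truth order parameter of 0.815, with
the 20° mean orientation recovered within ~2°. Group comparison with
the automatic selector:

```r
set.seed(1)
select_and_compare(rnorm(20), rnorm(20, 1))
#> <st_test> student_t: statistic -2.845, p = 0.007116 (alpha 0.05) *
#>   trail: shapiro_p_a=0.4194558, shapiro_p_b=0.312655, normal=TRUE,
#>          levene_p=0.8130059, equal_variance=TRUE
```

The whole analysis — simulate, score, classify, profile, crossings,
fibril cohorts, summary JSON — runs from one call:

```r
run_pipeline(list(out_dir = "run1", seed = 1))
```

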