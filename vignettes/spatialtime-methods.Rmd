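---
title: "Region-referenced gradient analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-referenced gradient analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialtime)
```

This vignette is the package's own account of its methods: the model
behind each stage, the parameters that matter and their defaults, what
the synthetic generators do and do not emulate, and the choices made
where the design was genuinely open.

## The SpatialTime axis

The analysis treats a marked tissue region — in the motivating setting,
the heterotopic-ossification anlagen at a tendon injury site — as a
spatial landmark and re-expresses every spot's position as a scalar
distance to it. For spot center $x_i$ and region raster $R$,

$$d_i = \min_{p \in R} \lVert x_i - p \rVert,$$

spot-center to pixel-center, in full-resolution pixel units; no
physical-unit conversion is applied. Coordinates are 0-based with $y$
increasing downward, matching how array-based platforms reference spot
positions to the tissue image. Distances are then min–max scaled so the
axis always spans exactly $[0, 1]$; the affine map preserves rank
order. Scaling over the analyzed spot set (rather than dividing by the
maximum alone) is deliberate: it guarantees both endpoints are attained
regardless of the raw distance range.

Two conventions are offered for spots inside the region. The default
gives them distance 0 (the minimum over region pixels). With
`signed = TRUE` interior spots instead receive minus their distance to
the region's complement, so the region border falls at a positive
SpatialTime and profiles can be read *across* the border — the
convention the bundled synthetic scene uses, because the
macrophage/MPC crossover it emulates happens at the border itself.
Which convention an upstream study used is rarely documented; offering
both, with unsigned as the default, keeps the default faithful to the
plain definition.

Degenerate input (all distances equal) maps every spot to 0 with a
warning rather than an error, so flat fixtures run end to end.

The implementation takes the exact minimum over all positive pixels,
vectorized in spot chunks; the test suite holds it to *exact* equality
with an exhaustive per-pixel scan, and to two structural properties:
growing the region never increases any distance, and joint integer
translation of spots and mask leaves distances unchanged.

## Spot classification and expression summaries

Label-transfer prediction scores in $[0,1]$ are consumed as input —
computing them is out of scope. A spot is cell-type positive when its
score reaches the 0.6 cutoff; the tie at exactly 0.6 counts as positive
(inclusive $\ge$), with a `strict` option since strictness at the
boundary is not standardized. Classification is per cell type with no
forced assignment: a spot may be positive for several types or none.

Counts are normalized by library size — each spot scaled to the median
spot total, then $\log(1+x)$. This is a deliberate stand-in for
whatever normalization an upstream single-cell pipeline would apply;
group summaries built on it (fraction of spots expressing, mean
normalized expression — the two numbers a dot plot encodes) are
comparable in rank and pattern, not in absolute units.

## Binned profiles along SpatialTime

Profiles use left-closed bins of width 0.01 on $[0,1]$ (the last bin
closed), i.e. exactly 100 bins, with per-bin count, mean, and standard
error using the sample standard deviation ($n-1$). The SE of a
single-observation bin is reported as `NA` and excluded from plots —
an undefined quantity is better than a zero. Two invariants pin the
implementation down: bin counts sum to the number of profiled spots,
and the count-weighted mean of bin means equals the global mean to
relative $10^{-9}$.

Smoothing is a centered moving average over the nearest `window`
(default 5) *non-empty* bins, with one-sided shrinkage at the profile
ends; window 1 is the identity and constants are preserved exactly. The
choice of smoother was open — a local-linear `loess` alternative is
available via `method = "loess"` — and the moving average was made the
default because it is parameter-light and exactly reproducible.

### Gradient features

The monotone trend is tested by Spearman correlation on the raw
spot-level pairs, not on the 100 bin means: binning would substitute an
arbitrary effective sample size into the p-value. Direction is
classified as

* **peaked** — the smoothed maximum is interior and exceeds both end
  levels by at least `prominence` (default 0.1) of the smoothed range;
* **increasing / decreasing** — otherwise, by the sign of a significant
  trend ($p < \alpha$, default 0.05);
* **flat** — no significant trend and no prominent interior peak.

The *end level* on each side is the smoothed maximum over the
`window`-many bins at that end, and the peak must lie strictly between
those end windows. Comparing against the single endpoint bin instead
turned out to be brittle: endpoint bins often hold one or two spots
(deep inside the region or at the far corner of the section), and a
single noisy spot there could manufacture a spurious "interior" peak
on a monotone profile. Relative prominence makes the rule
scale-free — multiplying all values by $c > 0$ scales bin means and
SEs by $c$ and leaves trend, peak location, and crossings unchanged,
which the suite checks. Note the consequence: on a pure-noise profile
with no trend, a random interior bump can legitimately classify as
peaked; the label separates shapes, it is not a significance test for
peaks.

Crossings of two profiles are located after min–max scaling each
smoothed curve over their common non-empty bins ("relative
expression"; the y-axis scaling of cross-profile comparisons is
otherwise arbitrary). Every sign change of the difference across
consecutive bins is interpolated linearly between bin centers;
tangential touches without a sign change do not count, and a run of
exact zeros between opposite signs resolves to its midpoint. Beyond
both gradients' support the scaled curves fluctuate around zero, so
spurious late-axis crossings can appear; the region-border crossover of
interest is the first crossing on the axis.

## Fibril anisotropy

Alignment of collagen fibrils in a grayscale image is summarized by an
averaged nematic tensor. Within an ROI the image is smoothed with a
3×3 mean prefilter, gradients are taken by central differences, and
each usable pixel contributes the outer product $t\,t^{\mathsf T}$ of
its unit tangent $t$ (perpendicular to the gradient). The unweighted
average over usable pixels is symmetric with trace 1; its eigenvalue
difference $\mathrm{AU} = \lambda_1 - \lambda_2 \in [0,1]$ is the
anisotropy score and the leading eigenvector the mean orientation,
reported in $(-90°, 90°]$ (nematic symmetry), counter-clockwise from
$+x$ with the image displayed y-up. Per-pixel normalization makes the
score invariant to intensity scaling. 0° = horizontal.

A pixel is *usable* when its gradient magnitude exceeds `grad_eps`
(default 0.05) of the ROI intensity range. This floor matters: with
unit tangents weighted equally, pixels whose gradients are numerically
tiny — background noise, ridge crests, and the cancellation zones
where the flanks of adjacent fibers oppose — contribute directions
that are essentially arbitrary and bias AU toward isotropy. On dense
synthetic fibril fields a floor of a few percent removes exactly those
pixels; with a near-zero floor (e.g. $10^{-6}$) the measured AU of a
strongly aligned field can drop by 0.2–0.3 for no optical reason. The
floor is exposed so users of sparse, high-contrast images can lower
it.

Second-derivative analysis is available as `method = "hessian"`: the
per-pixel tangent is taken perpendicular to the dominant eigenvector of
the local Hessian (the across-ridge direction). Descriptions of
fibril-alignment macros vary between gradient-based and Hessian-based
wording; both are implemented, the gradient form is the default, and on
strongly oriented patterns they agree.

Image-level AU is the unweighted mean over ROIs (1–8 accepted, 3–4
recommended; the weighting across sites is not standardized, so the
simplest rule is used). In the bundled cohort comparison the per-ROI
AU values are the unit of observation — quadrant ROIs of one image are
not independent samples of a population of fields, so the resulting
p-values carry the usual pseudo-replication caveat; the image-level
means are reported alongside.

## Group statistics

The two-group procedure mirrors common practice in this literature and
makes it deterministic and auditable: Shapiro–Wilk on each group at
$\alpha$ (a constant group counts as non-normal); if either rejects,
the two-sided Mann–Whitney U test is used — the non-parametric branch
takes precedence before any variance check. Otherwise a median-centered
Levene (Brown–Forsythe) test at $\alpha$ chooses Welch's t (unequal
variances) or Student's t. Which normality and variance tests to use
was open; Shapiro–Wilk and Brown–Forsythe are robust defaults, and the
recorded decision trail makes the selected branch fully reproducible.
All tests are two-sided at $\alpha = 0.05$; no multiple-testing
correction is applied to single comparisons (a Bonferroni multiplier is
available via `n_comparisons`). Under the null the selected test's
type-I error stays at the nominal level — the suite checks a rejection
rate within $[0.035, 0.065]$ over 2 000 seeded replicates. Multi-group
comparisons use ordinary one-way ANOVA; percent-positive cell
quantification is validated arithmetic, kept as a function so ROI
counts flow into the same test selector.

## The synthetic generators

The generators exist so that every downstream stage can be tested
against known ground truth. They emulate the *structure* of the study
inputs, not their full biology:

* **Layout** — a rectangular spot lattice (default scene: 50 × 40 =
  2 000 spots at pitch 10 px, a realistic section-scale grid) with a
  disk-shaped marked region (radius 60 px) that must lie inside the
  lattice; irregular regions enter through the polygon rasterizer
  instead.
* **Counts** — negative binomial with mean
  $\mu(s)$ from a gradient shape along SpatialTime and variance
  $\mu + \mu^2/\theta$ (default $\theta = 10$, moderate overdispersion
  typical of spot-level counts). Shapes: `decreasing`
  ($\mu = b + a e^{-(s/w)^2}$), `peaked`
  ($\mu = b + a e^{-((s-p)/w)^2}$), `flat`. The reference scene has a
  Thbs1-like gene highest at the region and steadily decreasing
  (amplitude 20, width 0.35) and a Thbs2-like gene peaking at
  $s = 0.30$ (amplitude 15, width 0.12) before decreasing again, plus
  20 flat background genes (baseline 5) so spot totals are dominated
  by an expression floor and library-size normalization behaves as it
  would on a real panel rather than on a two-gene composition.
* **Prediction scores** — a gradient profile plus Gaussian noise
  (default sd 0.05), clipped to $[0,1]$; the clipping bias near the
  bounds is accepted. The scene's macrophage-like field is high inside
  the region; the MPC-like field peaks just outside the border (at
  border + 0.05 on the axis), whose position is *computed* from the
  realized layout and returned as ground truth.
* **Fibril images** — straight fibers with orientations from a wrapped
  normal on the half-circle, sd $1/\sqrt{\text{concentration}}$
  radians (0 = uniform, $\infty$ = perfectly aligned), rendered with
  an analytic Gaussian cross-section (σ = 1.2 px) so intensity
  gradients point exactly across each fiber. By default fibers span
  the full field of view, as fibrils do in tendon imaging; this also
  avoids fiber end caps, whose radial gradient fields would otherwise
  contaminate the orientation statistics. The ground truth returned
  with each image is the nematic order parameter of the *sampled*
  angles, $\sqrt{\overline{\cos 2\theta}^2 + \overline{\sin
  2\theta}^2}$ — exactly the quantity the tensor eigenvalue difference
  estimates — so measurement fidelity can be asserted (the suite
  requires agreement within ±0.1 across a concentration grid).

Determinism is a contract: every generator seeds its own RNG stream,
and each gene or cell type derives a sub-stream from the seed and its
name, so adding a gene never perturbs the counts of the others. What
the generators do *not* emulate: read-level sequencing noise, spot
swapping or bleed-over, tissue morphology/H&E, curved or branching
fibrils, and imaging artifacts. Passing tests therefore demonstrate
correctness of the computations and recoverability of planted
gradients at realistic noise — not robustness to every failure mode of
real data.

## Pipeline and problem sizes

`run_pipeline()` validates its configuration before any stage runs
(cutoff 0.6, bin width 0.01, window 5, $\alpha = 0.05$ as defaults),
executes simulate/load → score → classify → summarize → profile →
features/crossings → fibril comparison, and writes CSVs plus a JSON
summary; every output carries the config hash and seed. The default
problem sizes — 2 000 spots, 22 genes, 192-px fibril images, 2 000
replicates for the type-I check — were chosen so that planted effects
are recovered with comfortable margins while a full run completes in
well under a minute on one CPU.

## Known limitations

* Distances are straight-line Euclidean; no geodesic/within-tissue
  distance is attempted.
* The analysis is strictly one-dimensional along SpatialTime; no 2-D
  spatial smoothing or spatially-variable-gene testing.
* Library-size + log1p normalization is a stand-in; absolute expression
  summaries are not comparable across normalization schemes.
* GeoJSON regions use the outer ring only; regions with holes are not
  supported.
* The peaked/flat classification is a shape label, not a peak
  significance test.
* Per-ROI anisotropy observations from one image are pseudo-replicates;
  interpret cohort p-values accordingly.
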