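---
title: "Curved-lane segmentation, band extraction and genotype calling"
author: "gelcaller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curved-lane segmentation, band extraction and genotype calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelcaller)
```

This vignette explains the models and procedures behind `gelcaller`, the
assumptions they rest on, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Conventions

Images are matrices of 8-bit intensities; rows are the migration axis with
the wells at row 1, columns run across the lanes.  The R API is 1-based
(idiomatic for matrix code); every file the pipeline writes uses 0-based
pixel coordinates, stated in the file itself.  All internal processing
assumes the **bands-bright** polarity: bands are intensity maxima, so lane
boundaries are *minima* of cumulative column profiles and bands are
*maxima* of lane profiles — one convention for both stages.  Silver-stained
PAGE scans (dark bands on light background) are inverted on entry by
`normalize_polarity()`.

The `auto` polarity mode infers the input convention from the cumulative
row profile `r(m)`: bands are thin horizontal stripes, so after removing
the slowly varying baseline (`runmed`), band rows survive as spiky
residuals whose sign tells the polarity (positive skew: bands bright).
A symmetric residual falls back to bands-dark, the silver-stain default.
A simpler alternative — asking whether the darkest pixels are spatially
compact — fails on gels with a vertical exposure gradient, where the
extreme pixels are the top or bottom background rows, which are just as
compact as bands; the row-profile residual is insensitive to such
gradients, which is why it was chosen.

## Lane segmentation

The core assumption is that lanes are *locally* straight: within a
horizontal strip of suitable height, each boundary is a single column.
Curvature is handled by making the strips follow the banding pattern and
stitching per-strip boundaries into polylines.

**Strips.**  Rows whose smoothed cumulative intensity stands out from the
baseline mark high-contrast (band) regions.  Parameters: threshold
percentile (default 75), merge gap (5 rows), minimum strip height (8 rows),
fallback strip count (4, used when fewer than two band regions exist —
sparse or blank gels).  Two numerical choices matter:

* the baseline window for `runmed` is `max(31, 2*(H/16)+1)` rows — it must
  exceed a band region's height (band thickness plus the spread added by
  per-lane mobility offsets), otherwise wide regions are eaten by their own
  baseline and fragment;
* strip cuts are placed at the midpoint of the *low-contrast gap between
  regions*, never between region centres, so a cut cannot fall inside a
  band region and split its evidence between two strips.

**Boundaries within a strip.**  Lane boundaries are local minima of the
3-point-smoothed column profile, kept when (a) their topographic depth is
at least `prominence_frac` (default 0.05) of the profile range, (b) their
depth clears a robust noise gate (8 times the point-to-point noise level
`mad(diff(profile))/sqrt(2)` — a strip with no bands then degrades to the
outer boundaries alone rather than to noise lanes), (c) they are at least
`min_lane_width` columns from any deeper minimum, and (d) their valley
floor is narrower than `3 * min_lane_width`.  Rule (d) deserves emphasis:
when a lane carries no band within a strip, the lane and its two flanking
gaps merge into one wide valley whose minimum carries no boundary
information; such valleys are skipped in that strip and localized by the
strips where the lane does carry bands.  `min_lane_width` defaults to
`W / (4 * expected_lanes)` when the lane count is known, else 5 px.

**Stitching.**  Boundaries of adjacent strips are joined by minimising the
total horizontal displacement under an order-preserving assignment
(dynamic programming; skipping an element costs `max_drift`, so a feasible
match always beats leaving both sides unmatched; cost ties resolve toward
the leftmost match).  Matches farther than `max_drift` are forbidden;
unmatched boundaries are propagated vertically so every lane spans the
full height, and boundaries first seen in a lower strip are back-filled
upward.  `max_drift` defaults to 0.4 times the median boundary spacing —
a fixed small default would disconnect genuinely curved lanes whose
drift between strip midpoints exceeds it, while 0.4 of the lane pitch can
never jump to a neighbouring gap.  Two safeguards follow from the phantom
boundaries that band-free lanes can still produce: nearby chains tracking
within `max_drift` of each other are merged (preferring the detected
column in each strip), and chains detected in fewer than half the strips
are discarded.  Each surviving chain gets one vertex per strip midpoint
and is extended to the image edges along its end segments.

**Lane extraction.**  Each adjacent boundary pair delimits a lane; every
row's pixel run between the interpolated boundaries is resampled by
nearest neighbour to the lane's median width.  Nearest neighbour is
deliberate: it preserves 8-bit intensities exactly and cannot fabricate
interpolation artifacts; the sub-pixel geometric error is irrelevant at
band scale.  Lanes narrower than `min_lane_width` are dropped.

**Straight mode** is the same pipeline with one image-spanning strip.  On
gels whose lanes carry one band or none, curved mode legitimately
under-segments (there is nothing to stitch with) — straight mode is the
documented remedy, and the two modes agree exactly on undistorted gels.

## Band extraction

**Straightening.**  For each lane column `n`, the raw truncated-overlap
cross-correlation against a reference column is maximised over shifts
`k ∈ [−search_bound, search_bound]`; the column is then displaced by the
argmax so band content lines up with the reference.  Choices:

* the correlation is the raw inner product (a normalized variant is a
  config switch) and terms with either index outside the lane are dropped
  — the only reading that keeps the sum defined for negative shifts;
* `search_bound` defaults to `H/8`: searching the full `±H` makes the
  overlap degenerate at large `|k|` and invites spurious optima, and
  within-lane band distortion is a small fraction of the lane height;
* ties resolve to the smallest `|k|`, then the negative one — prefer the
  minimal distortion, deterministically;
* the reference column is the first whose variance reaches a quarter of
  the maximum column variance.  Lane crops extend to the gap centres, so
  the first column is background; with noise its variance is nonzero, and
  anchoring on it lets the flat background-overlap term dominate while
  noise occasionally drags individual columns a few pixels — which
  duplicates every band as a faint displaced copy.  Requiring a
  substantial fraction of the maximum variance guarantees a band-bearing
  anchor;
* vacated pixels are zero-filled, never wrapped (wrapping would fabricate
  bands at the opposite lane end).

**Band calling.**  Candidates are rows where the first derivative of the
summed lane profile changes sign from + to − (plateaus count once, at
their last row).  No minimum separation is imposed — this is what lets
doublets through.  Two filters follow: candidates at or below the
15th percentile of the profile's own values are discarded (the percentile
is computed per lane; a global percentile would couple unrelated lanes),
and the pipeline additionally gates candidates below
`median(b) + 5 * mad(b)`.  The robust gate is the operative defence
against background noise: any local maximum of a noisy background clears
a 15th-percentile bar essentially by construction (the bar sits inside
the background distribution), while the median+MAD floor tracks the
background level and fluctuation and is cleared only by real bands, which
stand orders of magnitude above it.  Raising the percentile never
increases the number of calls (monotonicity), and the gate does not touch
doublet resolution, which is a matter of separation, not amplitude.

## Genotype calling

**Registration.**  The leftmost lane anchors the gel.  Global alignment
maximises the inter-lane profile cross-correlation within `±H/8`; a local
pass re-maximises it inside the reference-band window (`±window`,
default 8 px).  Each lane's reference band is the detected band nearest
the expected position after both shifts; lanes without one are excluded
(with a message) — a lane that cannot be registered cannot contribute
comparable offsets.  Band offsets are positions minus the lane's own
reference position, so every included lane has exactly one band at
offset 0 and offsets are comparable across gels regardless of residual
alignment error.

**Clustering.**  1-D DBSCAN over all offsets.  ε is the range of
reference-band positions measured after the global shift but before the
local refinement: the reference band is the one band known to be identical
everywhere, so its residual scatter is a direct estimate of the mobility
error that clustering must absorb; measuring it after local refinement
would collapse it to zero by construction, hence the ordering, and a floor
of 2 px guards the single-tight-gel case.  minPts is the integer closest
to 10% of the lane count, floored at 2 because DBSCAN cannot form a
cluster from fewer than two points.  The classic algorithm assigns border
points to whichever core point claims them first, which depends on input
order; here a border point joins its *nearest* core within ε (ties toward
the smaller offset), making results permutation-invariant.  Cluster means
and variances are fitted directly from member offsets (no histogram
binning), the variance floored at 0.25 px² so a degenerate cluster still
defines a usable Gaussian.

**Classification.**  A band goes to the cluster maximising the Gaussian
density; exact ties go to the smaller mean.  Bands far from every cluster
are declared novel rather than forced into the model.  The gate is
specified as `max_z` nominal standard deviations (default 3) but applied
through the cluster's Student-t predictive distribution
(`s * sqrt(1 + 1/n)` scale, `n − 1` degrees of freedom, at the tail
probability of a `max_z`-sigma normal): with a cluster fitted from a
handful of lanes the variance estimate is itself noisy, and a literal
3-sigma-of-`s` rule rejects genuine bands purely through sampling error in
`s`.  For large clusters the two rules coincide; `max_z = Inf` disables
rejection entirely, recovering plain maximum-likelihood assignment.

A lane's genotype is its presence/absence vector over the non-reference
clusters; band intensity is recorded but not used in the call.  Lanes with
identical vectors share a group id, assigned in order of first appearance.
The cluster model round-trips through versioned JSON so one model can
classify further gels from the same experiment.

## The synthetic generator

`gel_spec()`/`generate_gel()` render gels with exact ground truth: lanes
of configurable width/gap on a background with a vertical gradient;
sinusoidal or slanted lane drift (shared across lanes, as gel-wide flexion
is); bands as Gaussian vertical cross-sections (sd `band_sigma`) on the
curved centerline, optionally bowed parabolically (`smile`) or split into
doublets; per-lane integer mobility offsets (what global alignment must
correct) and per-band Gaussian jitter (what DBSCAN must absorb); clipped
additive Gaussian noise; contamination speckles; bands-dark polarity by
default so the polarity stage is always exercised.  Generation is
deterministic given the spec seed and leaves the caller's RNG untouched.

Default study conditions: 12 lanes of 18 px with 8 px gaps on a 400-row
gel; a reference band at row 60 and species at 70/140/210 px below it;
three genotype patterns assigned round-robin; peak intensity 180 over a
background of 30 with 0.05/row gradient; noise sd 3 (a realistic
densitometer figure for 8-bit scans); sinusoidal drift wavelength 3 times
the gel height (gel flexion is a slow bow, and strips ~100 rows apart must
see per-strip drift below the stitching radius).  Validation studies in
the test suite use 20 gels of 8–16 lanes with drift amplitudes up to 0.6
lane widths, 12 lanes × 15 columns shift sweeps, doublet gaps of 3–10 px
at noise sd 5, 500 random DBSCAN instances of up to 30 points, and a
two-gel genotyping study (12 + 12 lanes, band jitter sd 1 ≈ a quarter of
the fitted ε) — sizes chosen so the whole suite runs in well under a
minute while leaving each property statistically meaningful.

What the generator does *not* emulate, and hence what passing tests do not
show: saturation and blooming of overloaded bands, intensity falloff along
a band, lane-specific smearing, correlated (streak) noise, and real
densitometer point-spread.  Band shape is exactly Gaussian, which real
bands only approximate.  Results on real gels therefore still depend on
sensible cropping (the generator's gels are born cropped) and on bands
being resolved in the analysed region.

## Known limitations

* Below the last band region the boundary polylines are linear
  extrapolations; on strongly curved gels the extrapolated tail can drift
  a few pixels off the true centerline, occasionally dropping row coverage
  of an edge lane slightly below full.
* Gels where most lanes lack most bands defeat curved mode (the strips
  have nothing to stitch); use straight mode, as the sparse-gel tests do.
* Band positions stay in pixels; no molecular-weight calibration is
  attempted, and no dendrogram/similarity tree is built — genotypes are
  presence/absence patterns only.
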