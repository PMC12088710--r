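---
title: "Methods: ray-cast plaque quantification and agreement statistics for OCT label maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ray-cast plaque quantification and agreement statistics for OCT label maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octquant)
```

# The measurement model

Intracoronary OCT produces cross-sectional frames of the coronary artery.
After multiclass semantic segmentation, each frame is an integer label map
over ten classes: background, lumen, guidewire artefact, side branch,
intima, media, lipid plaque, calcified plaque, thrombus and plaque
rupture. `octquant` turns such maps into clinically interpretable plaque
metrics and implements the statistics used to compare automatic
segmentations against expert readings.

All geometric measures are defined relative to the **centroid of the
lumen**: equiangular rays are cast from it outward and the class sequence
along each ray is recorded as radial intervals. This polar framing matches
how readers report plaque extent ("a lipid arc of 112 degrees") and makes
every arc measure invariant to rotation and translation of the frame.

The per-frame metrics are:

* **Arc** (degrees, per plaque class): cumulative angular extent of the
  sectors occupied by the class. When a plaque is visible on both sides of
  the guidewire shadow, the arc is measured continuously across the
  shadow (bridging).
* **Minimum fibrous cap thickness** (lipid) and **calcium depth**: the
  minimum over rays of the radial gap between the abluminal lumen border
  and the adluminal plaque border. Rays containing guidewire artefact are
  excluded — no tissue is measurable behind the shadow.
* **Calcium thickness**: the maximum over rays of the summed radial
  extent of calcium intervals.
* **Fibrous cap area**: the area labelled intima inside the lipid arc;
  **fibrous cap ratio**: cap area divided by lipid arc.
* **Lipid-rich plaque (LRP)**: lipid arc of at least 90 degrees
  (boundary inclusive).
* **Arc correspondence score** between a reference and a predicted sector
  set: twice the angular intersection divided by the sum of the arcs —
  a Dice coefficient on angular indicator sets, symmetric by
  construction.

# Numerical choices

**Coordinates and angles.** Pixels are (row, col), 1-based, centers at
integer coordinates; angles are measured counterclockwise from the +x
(column) axis with y pointing towards decreasing rows. Arc magnitudes are
rotation-invariant, so this convention is internal only.

**Ray casting.** Default 720 rays (0.5 degree bins), configurable. Labels
are sampled along each ray every 0.25 pixel with nearest-neighbour lookup;
categorical labels are never interpolated. Interval boundaries sit at
midpoints between adjacent samples, so a radial class boundary is located
to about an eighth of a pixel before pixel-staircase effects.

**Sector membership and edge refinement.** A naive rule — "a ray is
positive if any sample along it hits the class" — dilates every sector
edge by 0.3–0.6 degrees, because the sampled digital ray absorbs
staircase corner pixels up to half a pixel off the ray line; with two
sectors per class the cumulative arc error exceeded one degree in our
phantom experiments. The package therefore uses **pixel-center voting**:
each pixel of the class votes for the ray nearest its center angle, a bin
is positive when it receives a vote, and single-bin holes flanked by
positive bins are closed (one 0.5-degree bin is below the angular
resolution of the pixel grid at vessel radii — near cardinal directions
the gap between adjacent pixel columns can exceed one bin, which would
otherwise split a contiguous sector). Sector *topology* comes from these
bins; sector *edges* are then refined to the extreme pixel-center angles
within each run, giving sub-bin precision. With this estimator the
cumulative arc error on randomized phantoms stays below about 0.3
degrees.

**Guidewire bridging.** A maximal run of guidewire-positive,
class-negative bins flanked immediately on both sides by class-positive
bins is absorbed into one continuous (bridged) sector. Bridged spans
count toward the arc but contribute nothing to the cap area, minimum FCT
or thickness: no tissue pixels exist behind the shadow.

**Minimum/maximum statistics and pixelation.** The minimum FCT and
calcium depth are minima over hundreds of rays of a quantity whose
per-ray error is roughly plus/minus half a pixel (the rendered lumen and
plaque borders are staircases). Such minima are biased towards smaller
values by up to about one pixel; the package's phantom tolerance of 1.5
pixels for radial measures reflects exactly this. The same argument
applies (with opposite sign) to the calcium-thickness maximum.

**The 90-degree LRP boundary.** The refined sector edges are estimated
from pixel centers, so an arc that is *exactly* 90 degrees in the
continuous specification measures a few hundredths of a degree below 90
on a pixel grid, and the inclusive threshold then classifies it as
non-LRP. The flag is simply not identifiable from pixels inside a
tolerance band around the boundary; the recovery suite asserts the flag
only outside that band.

**FCT variant.** The gap is radial (along centroid rays) by default,
consistent with the ray-cast framing; `fct_mode = "edt"` measures the
shortest Euclidean distance between the lumen border and the plaque
border instead, as a sensitivity analysis. For concentric geometry the
two agree; for strongly eccentric lumina the EDT variant is smaller.

**Centroid.** The centroid is the mean of the pixel centers of the
largest 8-connected lumen component, computed after post-processing by
default (satellite lumen blobs are either filtered or ignored).

# Post-processing

Segmentation outputs contain small isolated false predictions.
`filter_small_components()` removes, for every class except background,
thrombus and plaque rupture, the 8-connected components smaller than
`min_area_mm2` (default 0.005 mm², i.e. 50 pixels at 10 µm spacing) by
relabelling them to the majority class of their outer border
neighbourhood (background on ties or when isolated). Thrombus and plaque
rupture are exempt because small genuine specks of those classes carry
diagnostic meaning. The threshold is expressed in mm² so behaviour does
not change with image resolution; its default is a package choice — the
value used by any particular segmentation pipeline is configuration.

Relabelling can merge components or create new sub-threshold ones, so a
single pass guarantees neither idempotence nor exhaustiveness; the filter
iterates to a fixed point (in practice a handful of passes), after which
it is idempotent, conserves the pixel count, and leaves no non-exempt
component below threshold.

# Agreement statistics

* **Per-frame Dice** per class with the frame categories TP (class in
  both masks), FP/FN (class in exactly one; Dice scored 0) and TN (class
  in neither; no score). Aggregation is reported both over TP∪FP∪FN and
  over TP only, because published Dice values are often ambiguous about
  the convention.
* **Identification metrics** (accuracy, sensitivity, specificity, PPV,
  NPV) as proportions with **Clopper–Pearson exact** 95% intervals from
  beta quantiles. The exact method was chosen because reconstructed
  internal-test intervals (e.g. 12.8–64.9% for 5/14) match it to the
  printed precision, while Wald or Wilson intervals do not.
* **Cohen's kappa** from the 2×2 frame-presence table, with a Wald CI
  using the Fleiss–Cohen–Everitt large-sample standard error.
* **ICC(2,1)**: single-measures intraclass correlation for absolute
  agreement in a two-way random model, from the ANOVA mean squares, with
  the McGraw–Wong F-based interval. Single measures is the standard
  choice for per-frame comparisons; absolute agreement penalizes constant
  rater offsets, unlike the consistency variant.
* **Bland–Altman**: differences are prediction minus reference; limits
  of agreement are mean ± 1.96 SD.
* **Consensus frames**: external testing without pixel labels is
  restricted to frames where two independent observers agree on class
  presence/absence; for continuous measures the observer mean serves as
  reference.

# The phantom generator

`phantom_spec()` describes a synthetic vessel: a circular lumen disc
(optionally off-center, emulating eccentric catheter position), an intima
and a media annulus, angular plaque sectors with prescribed cap thickness
and plaque thickness, an optional guidewire wedge that shadows everything
behind the lumen border, an optional side-branch wedge, and optional
isolated speckle blobs placed at least 5 px from all structures by seeded
rejection sampling. Within plaque sectors the media is interrupted,
mimicking the signal attenuation behind plaque in real OCT.

Defaults emulate Dragonfly-class imaging: 10 µm isotropic pixels and a
4.5 mm field of view; the randomized generator draws lumen radii of
0.8–1.2 mm, intima 0.15–0.25 mm, media 0.08–0.12 mm, sector extents of
20–110 degrees, caps of 50–150 µm and plaque thicknesses of 0.25–0.5 mm —
ranges a reader would call representative for non-culprit coronary
lesions. Sectors and wedges are separated by at least 6 degrees so that
every ground-truth metric stays in closed form.

Every metric of a rendered phantom is known analytically
(`phantom_ground_truth()`, `analytic_cap_area()`); the property suites
assert recovery within ±1 degree for arcs, ±1.5 pixels for radial
measures and ±3% for the cap area, plus rotation and translation
invariance.

What the phantom does *not* emulate: OCT signal intensities, speckle
texture, light attenuation, non-circular lumina, tapering vessels, or
segmentation-model failure modes (e.g. lipid hallucinated behind
calcium). A green phantom suite therefore establishes that the
*measurement layer* is correct — not that any particular segmentation
model is accurate, and not the package's agreement with human readers on
clinical data.

# Simulation scales in the test suite

The statistics oracle suite verifies kappa against its brute-force
definition on every 2×2 table with n ≤ 50, ICC(2,1) against the
variance-component ratio σ²_subject/(σ²_subject + σ²_rater + σ²_error)
on simulated two-rater data (500 subjects, 200 replicates; subject SD 10,
rater SD 2, error SD 3), and Bland–Altman against simulated bias. The
ICC implementation is additionally checked against values frozen from an
independent reference implementation on a fixed 12-pair dataset. The
randomized phantom-recovery suite uses 50 specifications under a fixed
seed; these sizes keep the full test run under two minutes on one CPU.

# Known limitations

* Only Cartesian label maps are handled; polar-native (r, θ) OCT data
  must be converted upstream.
* Anisotropic pixel spacing is rejected rather than resampled.
* DICOM pullbacks are not read; masks travel as indexed PNG (+ YAML
  sidecar for spacing) or uncompressed single-frame NIfTI-1.
* No segmentation model ships with the package; `stack_frames()` defines
  the 7-frame pseudo-3D input contract a segmentation backend would
  consume, nothing more.
* Longitudinal (volumetric) integration is left to the caller: per-frame
  areas and the pullback frame pitch make trapezoidal volumes a one-line
  consumer computation.
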