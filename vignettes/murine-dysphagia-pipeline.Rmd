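---
title: "Quantifying murine feeding, swallowing and airway function: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying murine feeding, swallowing and airway function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murivfss)
```

## Scope

`murivfss` re-implements, as tested and reusable code, the quantitative
analyses used to characterize dysphagia in adult mouse models (such as the
*LgDel* model of 22q11.2 deletion syndrome): videofluoroscopic swallow study
(VFSS) jaw kinematics, endoscopic glottal-motion analysis, a lung-inflammation
pixel-ratio pipeline for H&E histology, home-cage behavior summarization, and
the group statistics layer. Because per-animal recordings from such studies
are typically not deposited, the package ships seeded synthetic-data
generators for every input modality; every analysis stage is validated
against the generators' ground truth rather than against archived recordings.

This vignette records the models, the tunable parameters, the numerical
choices, and the places where the original interactive workflows left the
algorithm under-specified and a concrete decision had to be made.

## Jaw kinematics (drinking and eating)

### Signal model

The jaw gape signal is the calibrated Euclidean distance between an upper
and a lower jaw marker, in mm per video frame (30 fps is the conventional
recording rate). The synthetic generator uses a raised cosine,

$$g(t) = b + \tfrac{A}{2}\,\bigl(1 - \cos 2\pi f t\bigr),$$

with baseline gape $b$ (mm), peak-to-trough amplitude $A$ (mm) and lick rate
$f$ (cycles/s). This matches the cyclic open/close pattern of real licking
and has analytically known extrema: minima ("closed", the lick event) at
$t = k/f$ and maxima ("open") at $t = (k + \tfrac12)/f$. Generator defaults
are realistic adult wild-type drinking values: $f = 8.71$ licks/s, $A = 3$
mm, $b = 0.5$ mm, 30 fps. Synthetic swallows are placed at every $n$-th
cycle minimum — the "rest frame" immediately preceding bolus transfer — with
the esophagus-entry frame a configurable integer number of frames later
(default 3 frames = 100 ms at 30 fps).

### Clip conventions

Analysis episodes start at a swallow event. The analysis window spans 2 s
(drinking) or 20 s (eating) from the swallow frame; five context frames are
attached to each end of the spliced clip for frame-by-frame review and are
*never* included in metric computation (`splice_clip()` keeps the window and
the clip separate, and the test suite asserts metric invariance to context
frames).

### Event detection

Open/close events are alternating extrema with a prominence floor,
defaulting to 20% of the clip's value range — small enough to keep genuine
cycles at 5% measurement noise, large enough to reject noise wiggles.
Two numerical details matter:

* **Plateaus** are collapsed to their first sample before extremum
  classification, so flat-topped peaks yield one event with a deterministic
  timestamp (the earliest sample of the plateau).
* **Boundary samples** count as events only when their value lies within
  the prominence floor of the nearest interior extremum of the same type.
  A clip that starts at a swallow starts at a true gape minimum, and that
  first sample must be counted for per-second cycle counts to be exact; a
  clip cut off mid-phase must not contribute a spurious event at its end.

Detected events can be edited (`add_cycle_event()`, `remove_cycle_event()`),
mirroring the manual review step of interactive tracking interfaces.

### Metric definitions and tie-breaks

A cycle is timestamped by its *closing* minimum (the completion of a lick).
Where the published operational definitions leave assignment ambiguous, the
package fixes it as follows:

* Per-second counting uses half-open sub-windows $[0,1), [1,2)$ of the
  analysis window; lick rate is the mean of per-sub-window close counts and
  swallow rate the analogous mean for swallows.
* The inter-lick and inter-swallow intervals are means of successive
  close-to-close and swallow-to-swallow gaps within the window (ms).
* The lick–swallow ratio counts cycles with close times in the half-open
  interval $(s_i, s_{i+1}]$ between successive swallows, so no cycle is
  double-counted across swallow pairs.
* Pharyngeal transit time is the mean of
  `(esophagus_entry_frame − rest_frame) / fps` over annotated swallows; it
  is always an integer multiple of the frame period.
* Jaw opening/closing velocities are per-phase mean slopes — gape excursion
  divided by phase duration for each close-to-open (opening) and
  open-to-close (closing) phase — not instantaneous derivative maxima. The
  operational reading of "speed at which the jaw closes during each cycle"
  is a per-cycle quantity, and mean slope is robust at 30 fps where a lick
  phase spans only 2–3 frames.
* Metrics that need swallows (inter-swallow interval, lick–swallow ratio,
  transit time) are *missing*, never zero, when the annotations cannot
  support them; per-mouse aggregation (mean over up to five drinking clips
  and one eating clip) drops missing clip values from the mean.

Note that lick rate and inter-lick interval are deliberately *not*
reciprocals: they are computed from different statistics of the same event
train (windowed counts vs mean gaps), and in swallow-aligned windows the
count-based rate can exceed $1000/\mathrm{ILI}$ by up to one cycle per
window. Published summary tables show the same mismatch.

### What recovery tests show

On noise-free synthetic traces every drinking metric is recovered exactly up
to the 1/30 s frame quantization; with Gaussian noise of 5% of the gape
amplitude, lick rate is recovered within 2% averaged over 100 seeded
replicates (4 s traces). These tolerances are consequences of frame
quantization, not tuned constants: the velocity bounds asserted in the test
suite are derived in closed form from the half-frame timing error and the
sampling error of the extremum value.

## Laryngeal kinematics

### Geometry

Three markers — left and right glottal edge (near the vocal process) and the
dorsal commissure (midline between the arytenoids) — define the analysis
geometry. Following the published procedure, the left/right points are first
adjusted to be equidistant from the commissure, moving the *nearer* point
outward along its ray to the distance of the farther point
(`adjust_glottal_points()`, an idempotent operation). The glottal axis is
fixed from frame 0 as the bisector of the angle at the commissure and is not
re-estimated per frame, consistent with tracking a fixed dorsal reference.
Each point's lateral coordinate is its signed perpendicular distance from
the axis (left negative, right positive); all laryngeal metrics are
therefore invariant to rigid translation and rotation of the whole scene,
which the test suite asserts.

### Metrics

Over a 10 s spontaneous-breathing clip:

* **MMRR** (mean motion range ratio): per consensus respiratory cycle, the
  ratio of the two sides' lateral ranges, averaged. The package uses
  min/max ordering (symmetric, ≤ 1), since reported normal values sit at or
  below 1; right/left ordering is available as an option.
* **OCCR** (open-close cycle ratio): right-side cycle count over left-side
  cycle count, in fixed right/left order since reported values straddle 1.
  Per-side counts use each side's own extrema (one cycle per
  abduction/adduction pair); the consensus segmentation is deliberately not
  used here because count asymmetry is exactly what OCCR measures.
* **Mcorr**: Pearson correlation of the per-frame first differences
  (velocities) of the left and right lateral coordinates on the shared
  image axis. This reproduces the documented semantics exactly: −1 for
  anti-phase (normal) motion, +1 for same-direction (paradoxical) motion,
  ≈ 0 for little or no motion. With strictly static traces the correlation
  is undefined and reported missing rather than zero.
* **VF angle**: the angle subtended at the commissure by the two points,
  per frame; per cycle its maximum and minimum are taken and averaged
  across cycles. Published summaries print a single "average VF angle"
  whose mapping to max/min is not recoverable, so the package reports
  `vf_angle_max`, `vf_angle_min` and their midpoint `vf_angle_mean` and
  leaves the mapping to the user.
* **Respiratory rate**: consensus cycle count (abduction peaks of the width
  trace) scaled to cycles/min.

Cycle segmentation for MMRR and the angle uses the glottal *width* trace
(right minus left lateral coordinate) as a consensus signal; a cycle window
runs from the width minimum preceding each abduction peak to the minimum
following it.

The laryngeal adductor reflex (LAR) is consumed as a manual annotation
(present/absent with start and end frames); its duration is
`(end − start)/fps · 1000` ms, missing when absent.

### Synthetic glottal motion

The generator oscillates both edges as raised cosines at the respiratory
frequency (default 150 cycles/min, a normal murine rate under light
anesthesia) about a resting half-width; in normal mode the sides move in
opposite image directions, in paradoxical mode in the same direction, so
velocity correlations are exactly ∓1 by construction at zero noise.

## Marker tracking

The original interactive software tracks manually seeded markers but does
not document its algorithm. The package's tracker is deliberately simple and
deterministic: normalized cross-correlation of a fixed $(2h+1)^2$ template
(default $h = 5$) captured in frame 0, searched within a radius (default
8 px) of the previous frame's position, with parabolic sub-pixel refinement
along each axis and the NCC score as per-frame confidence. The template is
never updated, so there is no drift; if the best score falls below the
confidence floor (default 0.5) tracking aborts with an error naming the
frame, mirroring the failure mode a human reviewer must resolve. The search
radius is a hard continuity contract: fixtures (and real clips) must not
move a marker more than the radius between frames. On rendered synthetic
videos with anti-aliased disk markers the tracker recovers trajectories to
well within 1 px, including half-pixel positions, which the parabolic
refinement recovers exactly for symmetric markers.

Calibration converts pixels to mm from a traced bar of known length
(10 mm) at the top of the first frame: `mm_per_pixel = bar_mm / bar_px`.

## Lung inflammation

The published quantification is an interactive image-editing recipe
(background removal, hue/saturation adjustments, brightness/contrast,
threshold 130). Slider semantics of interactive editors are not formulas, so
the package re-expresses the recipe as exact, testable math and rests its
validation on synthetic-truth recovery, not on bit-parity with any
particular editor:

1. **Background removal**: pixels matching the dominant border color
   (within a per-channel tolerance) *and* connected to the image border are
   flagged and whitened; interior pixels are never flagged. The border
   color must be bright (luminance ≥ 0.9 by default) to count as empty
   slide — an image whose border is tissue is left unchanged.
2. **Enhancement** in hue–saturation–lightness space: red-band pixels
   (hue ∈ [315°, 45°)) get saturation doubled (clipped); blue-band pixels
   (hue ∈ [195°, 255°)) are forced to white (saturation 0, lightness 1);
   then a global per-channel map $v' = \mathrm{clip}(2(v-128) + 128 + 150)$
   on the 8-bit scale polarizes the image. RGB↔HSL conversions are
   implemented in the package (base R provides only HSV) and round-trip to
   10 decimal places in the tests.
3. **Threshold**: inflamed pixels are non-excluded pixels with 8-bit
   luminance $0.299R + 0.587G + 0.114B < 130$ — the *dark* red/purple
   erythrocyte material is what survives the enhancement below threshold.
   The ratio divides by the total pixel count of the original, unedited
   image (per the published definition); a tissue-only denominator is
   available as an option and reported as such.
4. Five per-image ratios are averaged into one representative ratio per
   mouse.

The exact hue-band edges and the legacy brightness/contrast arithmetic of
the original editor are unrecoverable; the bands above are chosen to keep
dark red/purple material, delete blue, and polarize everything else, and
the pipeline is validated by recovering generated pool fractions (grid
0.01–0.2) within 20% relative error and monotonically.

The synthetic histology generator paints quasi-circular "erythrocyte pool"
regions of *exactly* the requested pixel count (the nearest-to-center pixels
of each pool are painted, so ground truth equals the target up to integer
rounding) on pink tissue inside a white border. It emulates color geometry
only — no staining variability, texture, or uneven illumination — so passing
recovery tests demonstrate correctness of the pixel arithmetic, not
robustness to real staining variation.

Mandible morphometry is a calibrated Euclidean distance between landmark
pairs (e.g. coronoid tip to mandibular head), scaled by a micrometer imaged
in the same session.

## Home-cage behavior

Event logs (class, start time, duration) emulate the export of automated
home-cage monitoring over 72 h. Events are credited entirely to the 24 h bin
containing their *start* time — exports deliver whole events, and splitting
is not part of the published procedure. Per class: per-bin frequency (count)
and duration (summed seconds); per mouse: the unweighted mean over the three
bins; conversions are exact rationals — events/hour divides the bin mean by
24 and minutes divides seconds by 60. A log-consistency linter (ordering,
overlap, range) substitutes for the manual video spot-checks of the original
workflow.

The generator draws each class as a Poisson process (defaults are the
wild-type rates: drinking 3.43/h, eating 19/h, grooming 16.11/h, with mean
durations derived from the corresponding duration means) with exponential
durations, then enforces the one-animal non-overlap invariant by thinning:
an event starting before the previous event ends is dropped. Thinning means
*realized* per-class rates sit a few percent below nominal when total
occupancy is non-trivial (grooming dominates); single-class recovery tests
therefore use single-class specs, and specs whose expected occupancy
exceeds 50% are rejected as infeasible.

## Statistics layer

Group comparisons are classic equal-variance independent two-sample t-tests
(the default of the point-and-click packages conventionally used for such
studies), reported as mean ± SEM per group with two-sided p-values at
α = 0.05; Welch's correction is available via `var_equal = FALSE`. Normality
is screened (Shapiro–Wilk) and reported but never used to auto-switch tests;
outliers beyond 1.5 IQR are flagged but retained. No multiple-testing
correction is applied by default, matching the source workflow — p-values
are exported so any correction can be applied downstream. Bilateral mandible
measurements use a genotype × side two-way ANOVA with interaction (type-II
sums of squares via `car::Anova`, equivalent to the sequential decomposition
in balanced layouts). `group_metrics_table()` produces the tidy per-metric
summary (group means, SEMs, t, p) in the layout of the published summary
tables; genotype labels live in a separate column merged only at this stage,
mirroring a blinded workflow.

The test suite checks the t-test and ANOVA against textbook-formula
re-implementations to 1e-10 and the empirical type-I error of the group
comparison at α = 0.05 over 10,000 null simulations (n = 8 per group).

## Problem sizes and determinism

All randomness flows from a single integer seed per generator spec; the
RNG state is restored afterwards, so generators are pure functions of
(spec, seed) and identical calls are bit-identical. The shipped tests and
the acceptance script use deliberately small problem sizes — 1–4 s kinematic
traces at 30 fps, 10 s glottal clips, 30-frame 128×128 fixture videos,
200×200 histology images, 72 h logs, 100–1,000 randomized replicates for
property and oracle-equivalence checks, 10,000 null simulations for the
type-I error — sizes at which every expected value is analytically forced or
independently recomputable while the whole suite runs in well under a
minute.

## Known limitations

* The synthetic videos are high-contrast disks on a uniform background;
  they validate the tracking/calibration arithmetic, not robustness to
  fluoroscopic noise, occlusion, or marker appearance change. The fixed
  (non-updating) template and hard search radius are design choices suited
  to high-contrast markers.
* Swallow events, rotary-chewing episodes and LAR presence are consumed as
  manual annotations, as in the original workflow; the package does not
  detect them from video.
* The enhancement recipe is a defined re-expression, not a reconstruction,
  of an interactive editor's sliders.
* The behavior generator is a thinned Poisson process with no circadian
  structure; it validates binning and summarization arithmetic, not
  behavioral realism.
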