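---
title: "Methods: serial-section reconstruction and tracer-spread quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial-section reconstruction and tracer-spread quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices behind
`tracer3d`, in the order the pipeline runs them, together with what the
synthetic phantoms do and do not establish about real data.

## The measurement model

The pipeline starts from per-slice multichannel rasters: a nuclei channel
(tissue morphology), a tracer channel, and for lymph nodes an
autofluorescence channel. Intensities live on the 0–1 scale; physical
geometry is anisotropic, with defaults matching thick-section scanning:
70 µm slice thickness and 10.4 µm in-plane pixels for brain exports, 0.65
µm pixels for lymph-node cryosections. All downstream distances are in
micrometres with per-axis spacing applied — at these defaults a voxel is
~6.7× longer axially than in-plane, so voxel-index distances would be
meaningless.

## Rigid registration

Serial sections are mounted one per slide and digitized independently, so
each slice carries an unknown in-plane rotation and translation. Only rigid
alignment is attempted: elastic registration would chase genuine tissue
deformation, tears and missing fragments, corrupting the very geometry being
measured.

A transform is `T(p) = R(θ)(p − c) + c + (dx, dy)`, rotation about the
geometric image center, 0-based `(x = column, y = row)` coordinates. The
estimator maximizes normalized cross-correlation (NCC) — chosen because it
is invariant to the linear brightness differences that the separate
brightness-equalization step corrects — via a coarse-to-fine pyramid:
exhaustive angle × integer-shift search at the coarsest level (bounds
±24 px, ±12°, covering twice the per-slice misalignment the phantoms
draw), local grid refinement per level, then continuous Nelder-Mead
refinement at full resolution. Two details matter for sub-pixel accuracy:

* **Matched pre-smoothing** (Gaussian, σ = 0.8 px, both images). Candidate
  warps are bilinear resamples and therefore slightly blurred; correlating a
  blurred candidate against a pristine reference biases the rotation
  estimate by ~0.1–0.2°. Blurring both sides removes the asymmetry.
* **Interior-foreground support.** NCC is evaluated only on the eroded
  (4 px) Otsu foreground of the fixed image. Neighboring sections genuinely
  differ at the tissue outline (the section footprint changes slice to
  slice); including the boundary ring biases translations by a few tenths
  of a pixel per pair, which accumulates along the stack. If no usable
  foreground exists the estimator falls back to all pixels.

Stacks are registered by sequential pairwise estimation propagated outward
from the **middle slice** (halving worst-case error accumulation relative to
first-slice anchoring); all channels of a slice are resampled once with the
cumulative transform (bilinear; masks would use nearest-neighbor). On
phantoms with per-slice misalignments up to ±10 px and ±5°, cumulative
recovery errors stay below ~0.1 px and ~0.1°.

## Brightness equalization and volume assembly

Each slice of the nuclei channel is linearly rescaled so its foreground mean
matches the stack-wide median of foreground means. Foreground is the
slice's own Otsu split, which is scale-invariant — a slice dimmed or
brightened by any factor selects the same pixels. Slices with zero
foreground mean are left unscaled with a warning. Other channels are never
touched.

The brain mask is derived from the nuclei channel: global Otsu threshold,
largest 6-connected component, then per-slice hole filling — interior
voids (vessels, ventricles, staining gaps) belong to the brain volume for
distance purposes. Maximum projections map array axes to anatomy for a
horizontal-section series: `horizontal` projects along the slice axis,
`coronal` along rows (anteroposterior), `sagittal` along columns
(mediolateral).

## Segmentation and the hemisphere split

A voxel is tracer-positive iff its intensity is **strictly greater** than
the threshold and it lies inside the brain mask. The default threshold is
Otsu's method (maximizing between-class variance, ties broken toward the
smallest candidate) on the masked histogram; a manual override is provided
because the binarization of the brain channel is the one stage for which no
documented method fixes the absolute counts — absolute positive counts are
therefore not comparable across thresholding choices, and the spread
comparison is run at matched counts instead (below).

The hemisphere separation is a 2-D polyline in registered pixel
coordinates, extruded through all slices — the volumetric reading of a
separation line drawn once on a projection. Voxels exactly on the surface
are counted separately rather than assigned by tie-break, which makes the
conservation identity `ipsi + contra + on_surface = total` exact rather
than approximate.

## The spread statistic

For every masked non-positive voxel, the distance to the nearest positive
voxel is computed by the separable lower-envelope (feature-transform)
algorithm with per-axis spacing — an **exact** Euclidean distance
transform, not a chamfer approximation, so tests can demand voxel-for-voxel
equality with brute-force all-pairs search. Shorter distances mean the
tracer reached more of the brain.

Sampling is exhaustive by default; `n = 3450` with a seed mirrors analyses
that subsample a few thousand voxels per brain. Summaries use linear
interpolation of order statistics (R quantile type 7, recorded in the
output). Group comparison is Kolmogorov-Smirnov normality per group (with
Lilliefors correction, since mean and sd are estimated from the data),
Kruskal-Wallis omnibus on pooled voxel-level distances, then all pairwise
Dunn tests with Bonferroni correction, α = 0.05 throughout and all tests
two-sided. Pooling voxels inflates the effective n — voxels within a brain
are pseudo-replicates — so per-brain medians are always reported alongside;
a mixed model of the brain/voxel hierarchy is deliberately out of scope and
the caveat is surfaced instead.

## Lymph-node quantification

True tracer is green-only; autofluorescent debris is bright in green *and*
red. The channels are first brought to a common brightness scale — red is
scaled by the ratio of median green to median red over red-foreground pixels
(red above its median + 6 MAD), compensating unequal exposure times without
letting background or green-only tracer drag the estimate; with no
appreciable red foreground the scale is 1. Then `green − scale·red` is
clipped at zero (the corrected image feeds a threshold on positive signal)
and Otsu-binarized.

Otsu always splits a histogram, even one containing only noise, so the
threshold must clear a **noise floor** before counting: the background of a
clipped difference image is `max(N(0, σ), 0)`, whose 90th percentile sits
1.2816 σ above the median, giving a robust σ estimate unperturbed by signal
occupying < 10 % of pixels. If Otsu's threshold falls below
`median + 6 σ̂` the image is declared signal-free and pixels above the
floor are counted instead (essentially zero), with a warning — this is what
makes "no detectable tracer" a stable, testable outcome rather than an
artifact of thresholding noise.

## Vessel vs. parenchyma intensity

Vessel / surrounding-tissue / artifact masks are user-supplied (vessel
identification is manual by design). Per region, intensity is summed over
non-artifact pixels and divided by the pixel area; regions pair within an
image, differences are checked with Shapiro-Wilk and compared with a paired
t-test, reporting the mean vessel-minus-tissue difference. Group-level
aggregation of per-image differences uses the Mann-Whitney U test; it is an
unpaired test and is applied to independent per-image values, a point the
documentation flags because it is occasionally mislabeled as paired.

## Statistical routines

The named tests delegate to R's vetted implementations (`kruskal.test`,
`wilcox.test`, `t.test`, `shapiro.test`, `nortest::lillie.test`); Dunn's
post hoc test is implemented in-package (tie-corrected z on mean ranks,
Bonferroni multiplication capped at 1). Conventions: Wilcoxon signed rank
drops zero differences and uses the exact distribution up to 25 nonzero
differences without ties, Mann-Whitney uses the exact distribution for
groups up to 25 without ties; otherwise normal approximations with tie
correction, with the route recorded in the outcome. Every exact route is
cross-checked in the tests against full enumeration (all sign assignments /
all labelings) for n ≤ 8, and empirical type-I error at α = 0.05 is
verified to be nominal over 2000 null simulations at n = 20 per group.

## The phantom generator

The generator's role is to provide inputs whose every downstream answer is
known. Defaults are fixed study conditions, not tuning knobs:

* **Geometry** — 20 slices of 96 × 96 px at 70 / 10.4 µm: a field of view
  of ~1 mm around the injection site, large enough for the two spread
  patterns to separate yet small enough for exhaustive oracles.
* **Brain mask** — an ellipse stack forming an ellipsoid (axial semi-axis
  0.85 × stack depth, so end slices keep most of their footprint, as
  mid-brain horizontal series do) with a narrow midline notch making the
  hemisphere split unambiguous.
* **Diffusive mode** — the analytic Green's function rather than a numeric
  PDE: testable against closed form, with `D = 300 µm²/min` and
  `t = 30 min` giving a diffusion length `√(4Dt) ≈ 190 µm`, about a sixth
  of the field of view. The masked, voxel-discretized Gaussian is
  renormalized to total mass `M`; at `t = 0` the whole mass sits in the
  injection voxel.
* **Advective mode** — a Gaussian tube (σ = 25 µm) around a branching
  biased random-walk skeleton that crosses the midline (reach 700 µm, which
  is also the arclength decay constant), plus 10 % of the mass as a local
  injection-site blob (σ = 50 µm, truncated at 3σ like the tube deposits so
  the field's support is exactly the dilated skeleton plus the injection
  neighborhood). This is the simplest field reproducing transport along
  vasculature/fiber tracts to the contralateral hemisphere; it is not a
  hemodynamic model.
* **Corruption model** — per-slice rigid misalignment (zero-mean normal,
  σ = 3 px / 1.5°, truncated at ±10 px / ±5°), multiplicative brightness
  jitter (±15 %), additive Gaussian noise (σ = 0.02), 8-bit quantization.
  The nuclei texture combines coarse blobs with a fine cellular grain,
  shared across slices — neighboring sections look alike, and the grain
  provides the high-frequency content that makes rotation sharply
  identifiable, as nuclear texture does in real DAPI images.
* **Lymph nodes** — integer-centered non-overlapping discs (tracer:
  green-only; autofluorescent: equal green and red) in an elliptical node,
  so per-class pixel counts are exact disc-area multiples.

Everything is a pure function of the `phantom_spec` including its seed;
generators restore the caller's RNG state.

**What the phantoms do not show.** They contain no real anatomy, no point
spread function or bleaching, no tissue deformation (the rigid-residual
assumption is untestable against real slides that were coarsely pre-aligned
by hand), and no physiological transport model — the diffusive/advective
pair reproduces the *qualitative* live/dead contrast, so passing tests
establish that the pipeline measures such a contrast correctly when it
exists, not that any particular biological effect size is recovered.
Published absolute spread medians (~110–180 µm) and intensity differences
(0.251 / 0.114) derive from undeposited raw scans and are explicitly not
reproduction targets.

## Matched-count comparisons

Otsu thresholds adapt to each brain's histogram, so two phantoms with
identical mass can segment wildly different positive-voxel counts (a broad
faint field segments large; a bright sparse tube segments small), and the
distance statistic depends strongly on how many voxels are positive. The
live/dead discrimination analyses therefore binarize both members of a pair
at their k-th largest intensity (k = 2000), comparing spread at matched
positive-voxel count — the honest version of the contrast. The
demonstration pipeline keeps Otsu (with the counts reported next to the
thresholds) because that is the operational choice for real data.

## Problem sizes and determinism

Unit tests run phantoms of 8–12 slices at 48–96 px; oracle equivalence uses
100 random 8 × 8 × 4 volumes (distance transform) and 50 random 8-bit
histograms (Otsu); discrimination uses 20 seeded phantom pairs at the
default 20 × 96 × 96 geometry with 3450 sampled voxels per brain; type-I
error uses 2000 null simulations per test. These sizes were chosen so the
full suite exercises every contract in a couple of minutes on one core
while keeping every oracle exhaustive. The pipeline writes no timestamps
into its CSV outputs, and identical configurations produce bit-identical
files.

## Known limitations

* Sequential pairwise registration accumulates error on very long stacks;
  a global/groupwise refinement is not implemented.
* The hemisphere surface is a per-slice polyline extruded axially; a truly
  3-D curved separation surface is out of scope.
* The Mann-Whitney group aggregation of paired region differences, the
  voxel-level pooling in the spread comparison, and the small-n hemisphere
  count test are all computed as the workflow calls for, but flagged —
  none is a statistically ideal design, and the package surfaces the
  caveats rather than silently "improving" the procedure.
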