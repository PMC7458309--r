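---
title: "Quantifying arterial wall architecture in en-face OCT sections"
author: "arteriowall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying arterial wall architecture in en-face OCT sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arteriowall)
```

## The measurement problem

Full-field optical coherence tomography (FF-OCT) images a transverse
temporal-artery section en face, label-free, at micrometer resolution.
Contrast reflects local reflectivity, and in an intact artery the three
tunicae separate cleanly: a hypo-reflective lumen, a moderately reflective
intima, a hyper-reflective media, and an intermediate adventitia, with the
internal elastic lamina (IEL) visible as a thin hypo-reflective band at the
intima/media interface. Two quantities summarize the wall:

* the **intima-to-media thickness ratio** I/M, which separates thin-intima
  sections (I/M < 1) from intimal hyperplasia (1 ≤ I/M ≤ 2) and from the
  severe remodeling range (I/M > 2) seen in giant cell arteritis (GCA);
* the **180° rotational symmetry** of the fiber orientation field: in a
  healthy, approximately circular section, the dominant fiber orientation
  at any point is parallel to the orientation at its antipode through the
  lumen center. GCA remodeling into disordered reticular neo-intima
  destroys this match.

Because no public image data accompany these observations, the package
ships a synthetic phantom generator with exact per-pixel ground truth, and
every quantitative claim the package makes is validated on phantoms.

## The phantom generator

`generate_phantom()` renders a section as concentric annuli (circular by
default; an `ellipticity` stretch is available) with per-tunica mean
reflectivities on the 500–2000 arbitrary-unit scale on which en-face OCT
plot profiles are conventionally read. On top of the plateaus it adds:

* **oriented band-pass fiber texture** — patch-wise planar gratings in
  polar patches (64 angular sectors × 24 μm radial bands), wavelength
  12 μm by default, oriented tangentially plus a per-patch wrapped-normal
  jitter with standard deviation `disorder × 90°`. `disorder = 0` gives an
  exactly tangential ground-truth field; `disorder = 1` is near-isotropic.
* **the IEL** — a hypo-reflective annulus (default 7.5 μm wide,
  `iel_contrast = 0.4`) straddling the intima/media interface, so the dip
  minimum marks the interface itself.
* **vasa vasorum** — hypo-reflective discs with thin bright rims at the
  media/adventitia junction, diameters drawn within 20–80 μm, with red
  blood cells rendered as iso-reflective dots inside a hypo-reflective
  annulus.
* **noise** — per-slice multiplicative log-normal speckle
  (`speckle_sigma`, default 0.25, mean-preserving) plus additive Gaussian
  read noise (default 15 a.u.). Depth stacks default to 20 slices at
  1.5 μm spacing and 1.5 μm pixels, and mean z-projection then attenuates
  speckle by roughly `sqrt(20)`.

GCA-like remodeling (`neo_intima = TRUE`) collapses the intima/media mean
contrast below the boundary-detection threshold, replaces the tangential
texture of the two inner tunicae by isotropic reticular patches, and
fragments the IEL: the band survives on only ~18% of the circumference
(six random arcs). Fragmentation is the load-bearing choice: it makes most
radial profiles unquantifiable — the behaviour observed in GCA sections —
while leaving a minority of profiles measurable, which is what makes an
I/M ratio accessible at all in that class ("when data were accessible" is
the clinical reality this mirrors). The retained fraction was fixed once
so that, with the detector defaults, roughly 80% of angles lose the
intima/media boundary while at least three complete profiles remain.

The cohort defaults in `default_class_specs()` draw true I/M uniformly
from [0.3, 0.8] (thin intima), [1.2, 1.8] (hyperplasia) and [2.5, 4.0]
(GCA-like), with per-class geometry ranges chosen so the thickest
admissible wall fits the default 640 px field of view. Per-sample seeds
derive from the master seed by a counter scheme, so cohorts are
reproducible and extensible without perturbing existing samples.

What the phantoms do **not** emulate: depth-dependent signal attenuation,
interferometric artifacts, mural thrombi, inflammatory cells (not visible
in this imaging mode), skip lesions, or non-annular wall geometry beyond a
global elliptical stretch. Passing tests therefore demonstrate that the
measurement chain recovers known architecture from OCT-like contrast and
noise — not clinical performance on real biopsies.

## The radial-profile protocol

`measure_layers()` emulates a contrast-based plot-profile protocol:

1. `estimate_center()` finds the lumen: the largest connected
   low-intensity region not touching the border (Otsu threshold), refined
   by a ±1.5 px sub-pixel grid search minimizing the angular intensity
   variance over concentric annuli.
2. `radial_profile()` samples rays at one-pixel steps (bilinear
   interpolation), smoothed by a 6 μm boxcar — wide enough to suppress
   projected speckle, narrow enough not to erode the IEL dip.
3. `detect_boundaries()` places boundaries at contrast ruptures: local
   extrema of the lagged finite difference whose magnitude exceeds
   `min_jump_fraction` (default 0.15) of the profile's dynamic range. The
   lumen edge is the first upward rupture, the outer edge the last
   downward one. The IEL is the *innermost* local minimum that undercuts
   the median level of its flanking plateaus by at least
   `min_dip_fraction` (default 0.25) of that level — a scale-free test
   calibrated so that fiber-texture dips (relative depth ≈ texture
   modulation, 0.18 by default, further attenuated by smoothing) fail it
   while a genuinely hypo-reflective band passes. The media/adventitia
   boundary is the strongest remaining qualifying rupture between IEL and
   outer edge. Boundaries that fail are flagged undetectable with zero
   confidence; a constant or chaotic profile returns a fully undetectable
   set rather than an error.
4. Thicknesses are averaged over three representative profiles out of 64
   candidate angles. "Representative" is operationalized as the three
   angles with the highest minimum boundary confidence
   (`selection = "best_confidence"`); fixed angles (0°, 120°, 240°) are
   available as a reproducible alternative. A section with fewer than
   three complete profiles is classed `unquantifiable`.

Class bounds sit in one table (`IM_CLASS_BOUNDS`): normal on [0, 1),
hyperplasia on the closed interval [1, 2], GCA-like on (2, ∞). The
endpoint convention (both 1 and 2 assigned to hyperplasia) is a package
choice, since "between 1 and 2" and "largely > 2" leave the endpoints
open; it is centralized precisely so it can be audited.

Measurements are taken along rays from the lumen center rather than along
normals to a fitted contour; for near-circular sections the two coincide
to first order. Adventitia measurement requires an outer downward rupture
to background; tissue touching the image border would be flagged rather
than truncated.

## Orientation mapping and the symmetry score

`orientation_map()` runs a quadrature Gabor bank: 18 orientations
(10° steps over [0°, 180°)), wavelengths {6, 12, 24} μm, one-octave
bandwidth, envelope elongated 2:1 along the stripes. Responses are
max-pooled over wavelengths (scale-invariant dominant orientation), the
argmax orientation is refined by three-point quadratic interpolation (so
downstream statistics are not quantized at the 10° step), and confidence
is the resultant length of the response mass in doubled-angle space — the
standard treatment for axial data, where angles are equivalent mod 180°.
Filtering uses FFT convolution with reflective padding; a border of half
the filter support, and pixels whose peak response falls below
`confidence_floor` (default 0.05) of the image maximum, are undefined.
The bank parameters are configuration, not claims: the smallest wavelength
resolves the default phantom fiber wavelength and the largest support
still fits inside the media band.

`render_orientation()` maps angle to cyclic hue (hue = angle/180) and
confidence to brightness, so a tangential field shows antipodally paired
colors and an isotropic field the rainbow-like appearance characteristic
of remodeled sections.

`symmetry_score()` quantifies the antipodal match. For each unordered
pair (p, p′ = 2·center − p) of defined, confident, in-mask pixels the
axial mismatch Δ ∈ [0°, 90°] is computed, and

score = Σ w·cos²(Δ) / Σ w,  w = min(conf(p), conf(p′)).

cos² of the axial mismatch is the natural axial analogue of cosine
similarity (alignment of doubled-angle unit vectors) and gives clean
limits: 1 for a perfect match, 0.5 for independent uniform orientations,
0 for systematically perpendicular antipodes. Antipodes use
nearest-pixel rounding — axial angles do not average linearly, so
sub-pixel interpolation of angles is deliberately avoided. The default
mask is the wall annulus between the measured lumen and outer edges; when
boundaries are undetectable (the GCA case) the score falls back to the
whole confident region. `cohort_separation()` summarizes healthy-vs-GCA
scores with medians, IQRs, the rank-sum test and the threshold maximizing
balanced accuracy.

## Statistics

`rank_sum_test()` reports the Mann-Whitney U from joint mid-ranks with
medians and interpolated-quartile IQRs; the two-tailed p value is exact
(no ties, smaller group ≤ 8 — the regime of small biopsy series) or a
tie- and continuity-corrected normal approximation otherwise. The exact
branch is cross-checked in the test suite against a full enumeration
oracle over all rank assignments for group sizes up to 6.
`pearson_correlation()` reports r with the two-tailed t-transform p on
n − 2 degrees of freedom; the 0.05 level is only ever a report flag.

## Numerical and design notes

* Coordinates are R-native 1-based (row, col) with pixel centers at
  integers; angles are measured from the +col axis toward +row and
  reduced mod 180° where axial.
* All randomness flows through explicit seeds; identical specs reproduce
  stacks bit-for-bit, and `run_study()` with a fixed config reproduces
  byte-identical reports. Per-sample seeds are counter-derived within
  32-bit range.
* With texture enabled, annulus means equal the nominal plateaus only in
  expectation (random patch phases); the plateau-recovery test asserts a
  2% tolerance, and exact equality with texture disabled.
* Degenerate inputs are contracts, not crashes: constant sections refuse
  center estimation, constant profiles return undetectable boundary sets,
  empty antipodal-pair sets raise a descriptive error naming the cause,
  and per-sample pipeline failures flag the sample while the study run
  continues.
* Problem sizes used by the validation suites: full-scale cohorts are
  640 px × 20-slice phantoms, 20 per class under a fixed master seed for
  the cohort-median and thickness-correlation checks; unit tests exercise
  the same code paths on 256–448 px phantoms with fewer slices.

## Worked example

```{r example, eval = FALSE}
cfg <- study_config(seed = 1L)        # 6 + 6 + 4 samples, full pipeline
st <- run_study(cfg, out_dir = "results")
summary(st)
```

The per-sample table lands in `results/report.csv`, the cohort statistics
(group I/M medians and IQRs, pairwise rank-sum p values, measured-vs-true
thickness correlations, symmetry separation) in `results/summary.json`,
and a stage-level log in `results/run.log`.

## Limitations

The symmetry score is a bounded descriptive statistic, not a validated
clinical diagnostic. The texture statistics of real biopsies (fiber
wavelength, modulation depth) are unknown; the defaults are plausible
rather than fitted, and all of them are exposed in `phantom_spec()`.
Real GCA additionally shows features the generator does not model
(thrombi, skip lesions, transmural infiltrates), so cohort-level results
here bound what the measurement chain can do, not what a clinic would
observe.
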