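---
title: "Methods: from tube-rack pixels to salinity tolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tube-rack pixels to salinity tolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duckquant)
```

`duckquant` turns paired top/side photographs of duckweed culture
tubes into per-sample growth curves, relative growth rates (RGR) and
a per-clone salinity tolerance (EC50). This vignette explains the
models and the procedural choices behind each stage, the parameters
that matter, and what the synthetic fixtures do and do not emulate.

## Segmentation model

Plant material is separated from background by colour alone. The RGB
image is converted to CIE LAB (sRGB primaries, D65 white point, via
`grDevices::convertColor`) and only the a\* green–magenta channel is
kept, rescaled by the 8-bit convention a\* + 128. Healthy duckweed
fronds are strongly green (a\* around −40 for typical frond RGB), the
rig's neutral background and glare sit near 128, so a single dark
threshold on this channel is a robust classifier whenever the
lighting is controlled. There is deliberately no machine-learning
segmentation: the method assumes colour-stable illumination.

Tunables (config section `segmentation`):

* `threshold` (default **120**, range 0–255): a\* value below which a
  pixel is plant. The margin between green fronds (≲ 90) and neutral
  background (≈ 126–130) is wide, so the default tolerates
  considerable lighting drift; it is the single most important
  calibration value when adapting to a new rig.
* `min_size` (default **50 px**): connected components smaller than
  this are treated as noise (glare flecks, condensation). Small
  duckweed species may need this lowered; a frond of the target
  species covers hundreds of pixels at the default geometry.

Per-tube areas use three circular regions of interest along the rack
axis. A 4-connected component (labelled with `EBImage::bwlabel`) is
assigned to the ROI containing its centroid and its full pixel area
counts there; components whose centroid falls in no ROI are
discarded. This keeps each colony in exactly one tube even when it
touches an ROI boundary. One caveat follows from the rule: on
adversarial inputs, raising the threshold can merge two components
into one whose centroid exits the ROI, so per-tube monotonicity in
the threshold is guaranteed only for scenes whose plants are
separated — which tube geometry enforces in practice. Mask-level
monotonicity is unconditional.

## Mat depth and barcode identity

Side views serve two purposes. First, the depth of the floating mat:
the binary mask restricted to the tube's column range is scanned row
by row, and a row counts toward depth when its white-pixel count
reaches `row_threshold_frac` (default **0.5**) of the tube's pixel
width. The fraction encodes the intent that depth is only meaningful
once the culture spans the tube; sparse rows are ignored, and
qualifying rows need not be contiguous (a literal reading of the
row-inclusion rule; the alternative—requiring contiguity—differs only
when artifacts create isolated dense rows).

Second, identity. Tube labels carry Code128 barcodes. Because
exposure and label angle vary tube to tube, a single binarisation
often fails, so `decode_barcode_robust()` searches rotations (outer
loop, 0° first — cheap attempts first) against binarisation
thresholds (inner loop, defaults 60–220 step 20), decoding scanlines
of each variant and returning the first success. Rotation uses
nearest-neighbour resampling: at the small angles involved (±12°),
interpolation would blur 2–3-px bar modules more than aliasing does.
The Code128 encoder and run-length decoder are implemented in the
package (no R barcode library exists); the decoder normalises run
lengths symbol by symbol, so uniform scale and modest contrast
compression do not matter, and the symbology's checksum rejects
corrupted reads rather than returning a wrong identity.

## Curve assembly

A top-view tube shows no barcode, so identity must be carried across
views. The package's joining rule: each top camera is paired with a
fixed side camera (`cameras$pairs`, default 1↔2 and 3↔4), tubes keep
their position index within the frame, and the two exposures of a
pass are matched by nearest timestamp within `pair_tolerance_s`
(default **600 s** — passes are minutes apart, days are 24 h apart,
so the window is generous yet unambiguous). This pairing is the one
stage with no direct counterpart measurement to validate against; it
is therefore config-exposed and exercised end-to-end by the rendered
fixtures, where the true assignment is known. Records sharing a
barcode within one hour collapse to the later timestamp (re-shots);
curves are sorted by time and expressed in days elapsed since each
sample's first observation, since growth rates are per day.

## Growth statistics

Two rules clean the curves before any rate is computed:

* **Viability filter**: a sample must hold ≥ `min_area_px`
  (default **1000 px**) for ≥ `min_days` (default **15**)
  *consecutive* days. With imaging 5 days/week, "consecutive days" is
  interpreted as a run of consecutive *observations* whose calendar
  span reaches 15 days (`filter$mode = "span"`); a strict
  15-consecutive-observation variant is available
  (`mode = "count"`). The filter removes cultures that died of
  transplant shock or never grew.
* **Zero-area points** make ln(area) undefined; any window containing
  one is skipped rather than patched.

RGR is the slope of an ordinary least-squares fit of ln(area) on
elapsed days inside a sliding window of `window_days` (default
**10 d**), anchored at every observation (closed interval
[t, t + 10]), needing ≥ 3 points. Per window an adjusted
R² = 1 − (1 − R²)(n − 1)/(n − 2) is attached, and the sample's RGR is
the **maximum** windowed slope with adjusted R² ≥ `min_fit` (default
**0.8**), ties to the earliest window. Maximising over windows reads
the steepest sustained exponential phase and is insensitive to lag
phases before growth starts and to saturation after the mat closes;
the fitness gate keeps windows that straddle either regime from
winning. Samples whose every window fails the gate return a
non-selected sentinel and are excluded (rather than floored), on the
view that an unfittable curve carries no defensible rate.

When a dose kills every culture in the trial, that dose still carries
information — growth there is zero, not missing. For the lowest such
dose an RGR of 0 is substituted for every designed replicate, and all
strictly higher doses are removed (they duplicate the same
asymptote while multiplying leverage on the fit's tail). Lethality is
judged trial-wide by default, per-clone optionally.

## Dose–response model and EC50

Replicate RGRs against added sodium x are fitted per clone with the
five-parameter log-logistic

$$f(x) = c + \frac{d - c}{\bigl(1 + e^{\,b(\ln x - \ln e)}\bigr)^{f}}$$

with lower/upper asymptotes c, d, slope b, inflection e and asymmetry
f. Dose 0 is handled by the analytic limit (d for b > 0), never by
offsetting x. Fitting is Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with starts c₀ = min, d₀ = max, e₀ = geometric
mean of positive doses, f₀ = 1 and a multi-start over b₀ ∈ {0.5, 1, 2}.
Two numerical realities shape the implementation:

* With the usual 4–5 surviving doses the model is overparameterized,
  and the likelihood has a flat ridge along (e, f): the optimizer can
  reach the SSE floor yet stop on the iteration cap while e and f
  drift in compensation. The fitted *curve* — and hence the EC50 — is
  stable along the ridge, so a fit is accepted as converged when the
  optimizer reports a tolerance stop **or** when at least two
  independent starts agree on the SSE floor (within 1 %), and the
  best fit is polished by a warm restart.
* Flat data (zero response variance) short-circuits to c = d = mean
  with SSE 0 rather than exercising the optimizer on a degenerate
  problem.

The EC50 is defined against the *observed* mean RGR at 0 mM (default
`baseline_mode = "observed"`; the fitted asymptote d is available as
an alternative). It is found by bracketed root finding of
f(x) = baseline/2 on (0, 2 × max dose] at 10⁻⁶ relative tolerance; if
the curve never crosses the half-response there, the estimate is
flagged absent instead of extrapolated silently. Uncertainty comes
from a bootstrap (default **500** iterations): within each dose,
replicates are resampled with replacement to their original count,
the model refitted and the EC50 re-solved; failed refits are dropped,
not imputed, with the effective count reported and the SD flagged
unreliable if more than half fail. The resampling stream is fully
determined by one master seed, with per-clone streams derived
deterministically from it.

## What the synthetic fixtures emulate

The generator reproduces the screening design the analysis defaults
are calibrated for: 6 clones × 6 added-sodium doses
(0/50/100/200/300/400 mM) × 6 replicates = 216 cultures, imaged
5 days a week for 4 weeks (20 imaging days), with every dose
≥ 200 mM lethal. Growth follows
area(t) = A₀·exp(r·max(0, t − lag)) capped at a carrying capacity,
multiplied by lognormal noise exp(N(0, σ²)) — an exponential-phase
model with lag (transplant shock delays growth) and saturation (the
mat closes the tube). Defaults: A₀ = 1500 px (one starting colony),
capacity 60 000 px, σ = 0.05 (eyeballed magnitude of quantification
jitter from glare and meniscus effects), lag 0. Each clone's true
rate at dose x is an LL5 curve with c = 0, f = 1, b = 2.5; the most
tolerant clone is parameterized d = 0.27 day⁻¹, e = 141.3 mM so that
it grows at 0.19 day⁻¹ (70 % of its optimum) under 100 mM — the
calibration anchors of the emulated trial — and the clone panel
orders the others below it at 100 mM, with the least tolerant at
e = 105 mM. Lethal samples decay at 0.5 day⁻¹, dropping below the
viability threshold within days.

Scene rendering is deliberately minimal: neutral background, darker
tube rims, water tint, one green elliptical colony per tube with
per-pixel colour jitter around RGB (60, 140, 60), a green mat band of
exact row depth, Code128 labels at configurable rotation/contrast,
and a few glare speckles kept off the colonies. Ground truth is the
*rendered* pixel count, recorded after rasterisation, never the
ellipse formula. Simulated curve tables keep areas real-valued;
quantisation to integer pixels is applied only when scenes are
rasterised — which is where it physically happens.

What is **not** emulated: anti-aliased colony edges, condensation,
focus blur, tube curvature and refraction, overlapping fronds,
colour variation between healthy and stressed tissue. Passing the
fixture suite therefore demonstrates the pipeline's correctness —
exact area bookkeeping, depth and identity recovery, end-to-end rate
and EC50 recovery — not segmentation robustness on difficult real
photographs, which remains a calibration exercise per rig.

## Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to
run comfortably on one CPU: fixture images default to 480 × 1440 px
with a reduced 720 × 240 geometry for the rendered mini trial
(1 clone × 5 doses × 2 replicates × 20 days, ~160 images, under a
minute end to end), full-trial checks use the curve-level generator
(216 × 20 points, seconds), and bootstrap checks use 30–500
iterations as the property demands. Every stochastic step — curve
noise, scene jitter, resampling — is a pure function of the
configured seed; reruns are bit-identical, and the pipeline drivers
write a provenance sidecar (package version, config hash, seed) next
to their outputs.

## Known limitations

* The top↔side record pairing rests on a camera-pairing convention,
  not on a measured linkage; a mis-wired rig configuration would
  silently pair wrong tubes. The fixtures validate the rule, not the
  wiring.
* EC50s inherit the zero-substitution convention: with growth
  measured at 4 doses and zeros appended at the lethal dose, the
  five-parameter fit is an interpolation whose tail behaviour is
  weakly constrained between the last survivable and the lethal dose;
  bootstrap SDs quantify resampling noise, not this structural
  uncertainty.
* The barcode decoder handles Code128 only (sets A/B/C), which is
  what the labels use; other symbologies would need a new decoder
  backend.
* Depth is reported in pixel rows, uncorrected for tube curvature.
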