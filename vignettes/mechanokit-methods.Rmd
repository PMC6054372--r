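---
title: "MechanoKit methods: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MechanoKit methods: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(MechanoKit)
```

MechanoKit implements three quantitative pipelines around one biological
question — what changes when the talin R8 bundle, the DLC1 binding site,
cannot unfold under force — and pairs each with a synthetic-data generator
whose ground truth makes every stage testable. This vignette is the
package's own account of the models, the tunable parameters, the numerical
choices, and what passing tests do and do not demonstrate.

Units are fixed package-wide: nm, pN, s, K for the single-molecule code;
µm, nN and pixels for the pillar code (converted only at the force map);
normalized intensity for FRAP. Thermal energy is k_B = 0.0138065 pN nm/K
times temperature, 4.114 pN nm at the 298 K default.

## Worm-like-chain elasticity

Stretch segments are modelled with the Marko–Siggia interpolation

$$F(x) = \frac{k_BT}{L_p}\left[\frac{1}{4(1-x/L_c)^2} - \frac14 +
\frac{x}{L_c}\right],$$

the standard choice for unfolded polypeptide in single-molecule AFM; exact
numerical WLC solutions change fitted contour lengths by far less than the
trace noise here and are out of scope. The persistence length defaults to
0.4 nm (unfolded polypeptide) and is configurable everywhere; it is held
fixed during segment fits because co-fitting $L_p$ and $L_c$ on short noisy
segments makes contour-length *increments* unstable (co-fitting remains a
deliberate non-default). The inverse `wlcExtension()` is a vectorized
Newton iteration with a bisection safeguard, converging to 1e-9 relative;
the forward/inverse round trip is property-tested on a 1000-point grid.

The clamp arithmetic `residuesToContourGain(n, perResidue,
foldedCorrection)` converts a residue span to the contour its unfolding
releases. For the 124 residues bridged by the R7–R8 disulphide clamp the
plausible edges — 0.40 nm/residue with no folded correction, and 0.34
nm/residue with a 4.0 nm folded end-to-end correction — give 49.6 and
38.16 nm, bracketing the expected 38–50 nm loss of unfolding length. The
package defaults (0.365 nm/residue, 4.5 nm) sit mid-bracket; values outside
0.3–0.45 nm/residue warn rather than fail, since they are physically
implausible but not impossible inputs.

## The pulling simulator

Constant-velocity mode advances the piezo at $v$ (default 400 nm/s, the
study's retraction rate) and solves, each step, the force balance
$k_c(z - x) = F_{WLC}(x; L_c)$ between the cantilever spring (default
7 pN/nm, mid-range of the instrument's 4–10 pN/nm) and the WLC of the
currently unfolded contour — warm-started Newton with a bracket fallback,
tolerance 1e-10 pN. Each folded, unclamped domain unfolds with probability
$1 - e^{-k(F)\,dt}$ under Bell kinetics $k(F) = k_0 e^{F\Delta x/k_BT}$;
unfolding adds the domain's release to the contour instantly. Clamped
domains never unfold and contribute only their folded size. Refolding is
neglected: a single monotone retraction gives no opportunity for it.

Two bookkeeping choices matter for testing. First, one uniform draw is
consumed per domain per step whether or not the domain is eligible, so a
wild-type and a clamped construct simulated from the same seed produce
bitwise-identical traces up to the sample where wild-type R8 ruptures —
the cleanest possible A/B contrast. Second, Gaussian force noise is drawn
per step from the same stream, leaving the stored extension and the
ground-truth event table noise-free.

The fixed-timestep Bernoulli scheme is exact for constant hazard within a
step, so its error is the hazard's growth across one step. At the modal
rupture force $F^*$ the hazard equals $r\Delta x/k_BT$ ($r$ the loading
rate), hence the guard: simulation refuses when $k(F^*)\,dt > 0.1$, with
$F^*$ from the Bell–Evans closed form at the protocol's effective loading
rate (velocity times the series stiffness of cantilever and WLC, iterated
self-consistently at the stiffest, all-folded contour). Domains whose modal
force is zero — spontaneous unfolders — pose no resolution problem and are
exempt. The default dt = 2.5e-4 s leaves the default construct at
$k(F^*)dt \approx 0.065$. Ramp mode applies the force grid directly
(force control), which also permits a fully vectorized rupture draw; the
acceptance suite checks the resulting rupture-force distribution against
the analytic Bell–Evans density (mode within 2%, Kolmogorov–Smirnov
distance < 0.05 at n = 2000).

Kinetic constants for the talin bundles are not known quantities; only the
~20 pN rupture scale observed at this protocol constrains them. The defaults —
k₀ = 0.06 s⁻¹, Δx = 1.5 nm for the talin bundles; k₀ = 3.3e-4 s⁻¹,
Δx = 0.25 nm for the I27 fingerprints (canonical literature scale) — were
chosen once to place ruptures near 20 pN and ~200 pN respectively, and are
per-domain fields of the construct, not hidden constants. The default
construct mirrors the experimental one: an always-unfolded 30 nm handle
(HaloTag plus linkers), two I27 fingerprints, R7 (release 63.9 nm, set so
the wild-type talin release totals ~104 nm) and R8 (release
`residuesToContourGain(124, 0.36, 4.5)` = 40.14 nm, clampable). Detachment
is deterministic at 280 pN, above the I27 rupture range, followed by a
free-cantilever baseline.

## Trace analysis

Detection smooths the force with a Savitzky–Golay filter (cubic, default
window 11 samples) and scans for a local maximum followed by a drop of at
least `minDrop` completing within a bounded extension window; the scanner
then advances to the post-drop valley (the running minimum until the
smoothed force recovers by half the threshold), so one rupture yields one
event. The defaults (10 pN drop, 10 pN minimum peak) suit low-noise data.
For the study conditions — 5 pN force noise — the noise-matched setting
used by `runClampContrast()` and the acceptance suite is a 51-sample window
with a 7 pN threshold: the filter attenuates white noise by the factor
0.21 (square root of the summed squared impulse response), so 5 pN of noise
leaves ~1.05 pN on the smoothed trace and 7 pN is a ~7σ criterion, while
the smallest physical drop in this construct (a talin bundle rupturing near
15 pN) is ~9 pN. Occasional false events split a loading branch in two;
because increments are differences of consecutive fitted contour lengths,
such splits telescope out of the per-trace sum and are classified by their
near-zero increment.

Per-segment contour lengths are least-squares fits over samples whose force
lies in a band (default 5 pN to 90% of the segment peak; below the band the
WLC is insensitive to $L_c$, above it the pre-rupture kink distorts), by a
1-D golden-section search in $L_c$ — with $L_p$ fixed the problem is
smooth and unimodal. Segments with fewer than 10 usable samples are skipped
with a reason. Classification applies the fingerprint logic: increments of
24–32 nm rupturing above 120 pN are I27 fingerprints (canonical I27
behaviour; the thresholds are configurable), the last event is the
detachment, the remaining internal events are talin. A trace is accepted
only with ≥ 2 fingerprint events — the standard single-molecule evidence
criterion — and ≥ 1 talin event; the per-trace *unfolding length* is
defined as the sum of talin-classified increments, consistent with reading
the clamp contrast as the release the clamp suppresses.

Cohort histograms are fitted with a single Gaussian whose bin counts are
modelled as amplitude times the Gaussian probability mass per bin —
evaluating the density at bin midpoints biases the centre once the spread
falls below the bin width. For the same reason the default bin width is
data-driven (Freedman–Diaconis) rather than a fixed 5 nm: the generator's
trace-to-trace spread (~1–2 nm, pure instrument noise) is far narrower than
experimental histograms (±7 nm, which 5 nm bins resolve comfortably), and a
fixed-width default would leave the fit unidentifiable exactly in the
regime the tests exercise. Figure-style widths (5 nm lengths, 2 pN forces)
remain available as explicit arguments. Sample moments are always reported
alongside as a cross-check.

What the generator does *not* emulate: surface adhesion peaks, multiple
tethers, refolding during pauses, 1/f drift, or instrument servo artefacts.
Passing recovery tests therefore demonstrate the correctness of the
detection/fit/classification chain under the stated noise model, not
robustness to every artefact of real recordings — the fingerprint
trace-acceptance rule and the configurable thresholds are the knobs a real
dataset would need.

## Micropillar traction forces

The generator renders each frame as background plus one Gaussian spot per
pillar (σ = 1.3 px) at node + displacement + drift, plus i.i.d. Gaussian
intensity noise; defaults are a 12 × 12 array at 2 µm pitch, 15 nN/µm
pillars, 0.16 µm/px — plausible values for such arrays, since the study
defers its own to a methods reference. The demo contraction field pulls
cell-mask pillars toward the mask centroid with a sinusoidal time course
peaking at 1.5 px (0.24 µm, i.e. 3.6 nN at 15 nN/µm — a realistic
fibroblast scale); fields reaching half the pitch are refused as
untrackable. Ground-truth positions are stored with the stack.

Localization extracts a window per nominal node, estimates background from
the window border, initializes with the background-subtracted intensity
centroid, and refines with a least-squares 2-D Gaussian (Levenberg–
Marquardt); windows without signal above background return a flagged
missing position. `trackPillarMovie()` recentres each frame's windows on
the previous frame's positions so slow drift never walks a spot out of its
window. Linking is nearest-neighbour with a gate of half the pitch, ties
broken by distance and counted; missing detections are linearly
interpolated and flagged. Drift is modelled as rigid translation only — the
mean displacement (relative to frame 0) of ≥ 3 cell-free reference pillars,
subtracted from all tracks, leaving the mean reference displacement
identically zero. Forces multiply displacements (against the frame-0
zero-force reference) by the pillar stiffness, componentwise; the peak
force per pillar is the maximum magnitude over frames, and the cell-average
force is the mean of peak forces over cell-mask pillars (peak-then-average,
matching "maxima for each pillar"). Whether averaging should instead run
over time is a genuinely open reading; peak-then-average was chosen and is
trivial to change downstream since the full force map is returned.

Coordinates are x = column, y = row, 0-based, origin at the centre of pixel
(0,0). Known limitations: no pillar-bending theory (stiffness is an input),
no cell segmentation (masks are supplied or synthetic), no rotational
drift, and the Gaussian spot is an idealization of a bright-field pillar
image.

## FRAP

Curves follow the study's acquisition: five prebleach frames at 5 s
spacing, bleach, then 5 s frames for 100 s, t = 0 at the first post-bleach
frame. Normalization maps the prebleach mean to 1 and the background to 0
and is idempotent. Recovery is fitted as a single exponential
$n(t) = f + (p - f)(1 - e^{-t/\tau})$ — the reaction-dominant regime
appropriate to focal-adhesion binding turnover; a diffusion-coupled model
is a non-goal. The fit is profiled: at fixed τ the model is linear in
$(f, p-f)$, so a 1-D minimization over log τ with an exact linear solve
inside is deterministic and cannot fail to converge — important because the
null-calibration test runs thousands of fits. The immobile fraction is
$1 - (p - f)/(1 - f)$, clamped to [0, 1]; it is 1 with no recovery and 0
for full recovery, and decreases monotonically in the plateau.

The extra-sum-of-squares F test pools post-bleach *points* across each
group's curves (point-level pooling, matching a fit to "the best fit
lines"): SS_shared from one 3-parameter fit to both groups, SS_sep from one
per group, $F = [(SS_{shared} - SS_{sep})/3]/[SS_{sep}/(N-6)]$ referred to
$F_{3, N-6}$. With i.i.d. Gaussian noise and a correct model this is the
textbook nested-model test; the acceptance suite verifies its type-I error
at α = 0.05 lies in [0.03, 0.07] over 2000 null simulations, and its power
(immobile fractions 0.2 vs 0.5, 15 curves per group, noise sd 0.03) in the
module tests. Point-level pooling treats points within a curve as
independent; for real data with per-cell random effects the test is
anti-conservative, which is a property of the method being emulated, not a
bug — the synthetic generator deliberately matches its assumptions. No
acquisition-photobleaching correction is applied by default (the emulated
protocol reported an unbleached-region control rather than a correction).

The stain-ratio quantifier is background-corrected masked means,
numerator/denominator per cell, with non-positive denominators flagged and
excluded; its generator renders uniform disk "cells" with configured true
ratios.

## Problem sizes and reproducibility

All stochastic entry points take explicit seeds; datasets derive per-item
seeds deterministically from a master seed, so every result in the tests
and the acceptance script is reproducible bit-for-bit. The suite's sizes —
60 + 60 traces for the clamp contrast, 2000 ramp ruptures for the
distribution check, a 12 × 12 × 20-frame movie at SNR 20, 200 noisy FRAP
curves and 2000 null F-tests — were chosen as the smallest cohorts at which
the estimators' sampling error is clearly inside the tolerances being
asserted, and they match the spirit of the emulated study (82 and 56
traces; 14–33 cells per FRAP condition).
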