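# MechanoKit

Quantitative pipelines for a cellular mechanosensing question: what happens
when the talin rod's R8 bundle — the binding site of the RhoGAP tumour
suppressor DLC1 — is prevented from unfolding under force? A disulphide
clamp across the R7–R8 linkers (cysteines at positions 1459 and 1583) locks
R8 shut; the consequences are measured by single-molecule AFM on
polyproteins, by traction forces on micropillar arrays, and by FRAP of
GFP–DLC1 in focal adhesions. MechanoKit implements the quantitative
analysis behind each of those readouts, and pairs every stage with a seeded
synthetic-data generator carrying ground truth, so the whole chain —
simulation, detection, fitting, statistics — is verifiable without any
instrument data.

It is intended for single-molecule and mechanobiology groups who want a
tested, scriptable version of these analyses, or a benchmark harness for
their own.

## What is implemented

**Polymer elasticity and construct bookkeeping.** Marko–Siggia worm-like
chain: F(x) = (k_BT/L_p)[1/(4(1 − x/L_c)²) − 1/4 + x/L_c], its numerical
inverse (safeguarded Newton, 1e-9 relative), and the residue-count →
contour-length-gain arithmetic n·l_res − c_fold that brackets the expected
38–50 nm loss of unfolding length for the 124-residue clamped span.

**smAFM pulling simulator.** Constant-velocity retraction with a cantilever
spring in series with the WLC of the currently unfolded contour; Bell
kinetics k(F) = k₀·exp(F·Δx/k_BT) drive stochastic unfolding
(per-step Bernoulli with an accuracy guard on k(F*)·dt); clamped domains
never unfold; force-ramp mode and the equipartition stiffness calibrator
k = c·k_BT/⟨d²⟩ are included.

**Trace analysis.** Savitzky–Golay-smoothed drop detection, per-segment WLC
fits with fixed L_p, contour-length increments ΔL_c, I27-fingerprint
classification and acceptance, per-trace unfolding lengths and Gaussian
histogram fits (bin-integrated, so under-resolved histograms stay
identifiable).

**Micropillar traction forces.** Synthetic pillar movies (Gaussian spots,
contractile displacement field, rigid stage drift, shot-like noise),
centroid-initialized 2-D Gaussian subpixel localization, nearest-neighbour
track linking, drift correction from cell-free reference pillars, and
F = k·d force maps with per-pillar peak forces and the cell-average force.

**FRAP kinetics.** Prebleach/background normalization, single-exponential
recovery fits n(t) = floor + (plateau − floor)(1 − e^(−t/τ)) via a profiled
(linear-in-amplitudes) least squares, immobile fraction
1 − (plateau − floor)/(1 − floor), the extra-sum-of-squares F test between
conditions, and per-cell stain-ratio quantification (pMLC-2 / MLC-2 style).

## Worked example

The canonical in-silico experiment — wild-type versus clamped R7-R8 cohorts
through the full pipeline:

```r
library(MechanoKit)
res <- runClampContrast(nTraces = 20, seed = 1)
show(res$wt)
#> GaussianFit: mean 105.5, sd 0.9529 (n = 20)
show(res$clamp)
#> GaussianFit: mean 65.16, sd 0.4353 (n = 18)
res$meanDifference
#> 40.30
```

Twenty wild-type traces give a fitted mean unfolding length of ~105 nm
(R7 + R8 releases), the clamped cohort ~65 nm (R7 only; two traces were
rejected by the fingerprint criterion), and their difference, 40.3 nm, is
the contour release the clamp suppresses — the generator's ground truth is
40.14 nm, from 124 residues at 0.36 nm/residue minus a 4.5 nm folded-size
correction.

FRAP and calibration one-liners:

```r
fit <- fitRecovery(simulateFrapCurve(0.05, 0.65, 22, noiseSd = 0.03, seed = 4))
show(fit)
#> FRAPFit: floor 0.0515, plateau 0.662, tau 21.35 s, immobile fraction 0.356

equipartitionStiffness(0.4114, 298)   # cantilever spring constant, pN/nm
#> 10.00082
```

A YAML-driven runner chains the stages (`?runPipeline`), and
`inst/scripts/mechanokit-cli.R` exposes it to the shell.

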