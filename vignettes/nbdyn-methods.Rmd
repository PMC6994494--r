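---
title: "Models and methods behind nbdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nbdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific model behind each module, the
parameters that matter, the numerical choices, and — importantly — which
features of real data the synthetic generator does and does not emulate,
hence what a passing test does and does not establish.

## The system

Liquid-like nuclear bodies (NBs) are membrane-less protein condensates.
Three imaging read-outs characterize their material state:

* **Coordinated mobility at the boundary.** In fluctuation imaging, the
  per-pixel variance/mean ratio of a rapid time series (index of
  dispersion) is 1 for pure photon shot noise and rises wherever many
  fluorophores move together. For a liquid droplet this signal forms a
  ring at the phase boundary; a rigidified (stressed) boundary loses it.
* **Exchange dynamics by FRAP.** Bleaching a body and fitting the
  percentage recovery reports the mobile fraction (plateau) and the speed
  of exchange (initial rate over the first 15 s).
* **Morphometry.** Sizes (µm², equivalent diameter), size classes with
  boundaries at 0.75 and 2 µm, total NB load per nucleus, and
  background-corrected intensity ratios (Fn/c; RNA in NB vs nucleoplasm).

## The droplet simulator

### Particle dynamics

Particles diffuse in 2-D (the analyses operate on single confocal planes;
"spheres" are discs). Per simulation step of `dt` seconds a mobile
particle is displaced by independent Gaussian steps of standard deviation
`sqrt(2 D dt)` per axis, with `D = D_in` inside a droplet and `D_out`
outside. A step whose segment crosses a droplet rim is accepted with
probability `p_exit` (inside to outside) or `p_enter` (outside to in),
otherwise the particle is specularly reflected at the rim. The field edge
(or, when configured, a circular nuclear envelope) reflects.

Two numerical points matter:

* **Step-length correction.** Boundary *encounter rates* scale with the
  step length, i.e. with `sqrt(D)`. Raw acceptance probabilities would
  therefore equilibrate at a density ratio of
  `(p_enter/p_exit)·sqrt(D_out/D_in)` — with the defaults a factor ~63
  rather than the intended 20, approached over hundreds of seconds. The
  engine damps the faster side's acceptance by `sqrt(D_slow/D_fast)`, so
  the stationary in/out density ratio is exactly `p_enter/p_exit` and the
  stationary initialization below is consistent with the dynamics.
* **Fixed dynamic step.** The dynamics always advance at the simulation
  step (default 0.121 s, the frame time of the rapid acquisition),
  independent of how frames are spaced. FRAP protocols record frames 5 s
  apart; taking single 5-s Brownian steps would produce ~2 µm jumps for
  which rim-crossing logic is meaningless.

Particles are initialized by a multinomial draw over regions with weights
`area × (p_enter/p_exit)` inside each droplet and `area × 1` outside (the
detailed-balance ratio, exact after the correction above), then
equilibrated for 200 burn-in steps before recording; moment maps are
therefore free of initialization transients.

An `immobile_fraction` of particles never moves — the ground truth behind
FRAP's immobile pool.

### Interfacial remodeling events

With independent particles and a geometrically static rim, the
variance/mean map has *no* boundary ring: an ideal-gas field gives
`ratio = 1 + brightness × (PSF overlap)` independent of the local density,
on either side of a density step. The boundary signature in real
fluctuation data comes from *collective* motion of the interface itself.
The simulator models this explicitly: each droplet's rim undergoes
discrete remodeling events — capillary-wave-like protrusions — that are
Poisson in time (default 0.05 events per µm of perimeter per second,
about four per 10-s segment on a 1.5-µm body) and uniform in angle. One
event lasts 1.5 s and displaces rim-proximal particles radially outward
by up to 0.4 µm (half-sine in time, Gaussian tapers of 0.6 µm along the
arc and 0.25 µm radially), applied at render time so trajectories and
partitioning statistics are untouched. Event amplitude scales with the
phase contrast `1 − p_exit/p_enter`: a kinetically transparent "droplet"
(`p_exit = p_enter`) has no interface and renders invisibly, as it must.

The condition presets tie everything to one ground-truth number. The
`control` preset leaves boundary mobility alone; the `stress` preset
multiplies it by 0.2 — both the crossing probabilities *and* the event
sequence, the latter by thinning, so a stress run's events are a strict
subset of its seed-matched control run's. The event *rate* is kept in the
sparse regime deliberately: when at most a few events hit a segment, the
frequency of high-ratio boundary pixels responds approximately linearly
to the event rate, so the measured control/stress frequency fold-change
recovers the five-fold ground-truth reduction. Two effects bias the
recovered fold downward of 5 (typically to about 4): event footprints
overlap within control segments (Poisson coverage saturation, which only
affects the denser condition), and the dispersion-estimator noise floor
adds to both conditions' frequencies. Both are documented behaviour of a
thresholded, saturating statistic, not of the underlying mobility.

### Detection

Each fluorescent particle contributes an isotropic Gaussian PSF
(σ = 0.21 µm ≈ 1 pixel at the default 13.5 µm/64 px calibration)
integrated per pixel via the Gaussian CDF and scaled by `brightness`
(counts/fluorophore/frame); a uniform `background` is added and each
pixel value is drawn Poisson (`noise = "poisson"`) — so with zero
particles the variance/mean ratio calibrates to 1. An optional
`acq_bleach` probability photobleaches each fluorophore per recorded
frame, reproducing the slow decay of long confocal series; a reference
ROI (double normalization) divides it out.

Randomness is split into five deterministic sub-streams (placement,
diffusion, bleaching, detection, interface) derived from the one seed, so
e.g. switching the detector's noise or the preset does not perturb
seed-matched trajectories.

### What the generator does not emulate

No 3-D optics or axial drift, no scan-line temporal skew within a frame,
no detector gain/afterpulsing, no fluorophore blinking, no Ostwald
ripening, no cell movement, and the remodeling events are a stylized
stand-in for true interfacial hydrodynamics. Tests passing on this ground
truth validate the *analysis pipeline's* correctness and sensitivity, not
the biological realism of any particular parameter value; absolute rates
and brightnesses are configurable, not measurements.

## Moment analysis

`moment_map()` computes per-pixel mean and *population* variance
(denominator N, the number-and-brightness convention) with a single-pass
Welford accumulation, vectorized over pixels; it agrees with a two-pass
oracle to better than 1e-9 relative error. Pixels with mean ≤ `mean_floor`
(default 1 count) are invalid — the ratio of a near-zero mean is noise.
`segmented_moments()` tiles the acquisition into consecutive 80-frame
segments (~10 s), dropping the remainder (floor semantics; 1000 frames
give 12 maps covering 960 frames).

`high_ratio_frequency()` reports the fraction of valid pixels above a
threshold. The "high" cutoff is adaptive: the 95th percentile
of a disjoint reference region (droplet interior or nucleoplasm), pooled
across segments for a series so all segments share one threshold; an
absolute override is available. Degenerate masks (no valid pixels) raise
typed errors rather than returning NaN.

Two mask conventions are used around a rim of radius R with PSF σ:

* *Localization* checks use the annulus R ± 2σ, judged within the body's
  vicinity (r < 2R): farther out, the heavy single-pixel tail of an
  80-frame dispersion estimate over thousands of dim pixels outnumbers
  any rim signal by area alone and says nothing about the boundary.
* The *frequency fold-change* between conditions is measured on the outer
  rim skirt [R + σ/2, R + 3σ], with the boxcar detrend enabled. The inner
  skirt overlaps the bright interior, whose estimator spread sets a noise
  floor that compresses the measurable fold; the outward remodeling
  protrusions live in the outer skirt, where the dim nucleoplasm makes
  the estimator tightest, and detrending strips slow pool/exchange drift
  that would otherwise register as dispersion.

`boundary_axis_profile()` samples the ratio image at 1-pixel steps along
a user axis with NA-aware bilinear interpolation, averaging over a
perpendicular band (± `band_halfwidth` pixels, default 2); positions are
reported in µm from the first endpoint. Coordinates are 0-based
(row, col); a pixel's centre sits at `(index + 0.5) × pixel_size`, with
x = columns and y = rows.

No detrending or bleaching correction is applied before the moments by
default: the 10-s segments bound drift by construction, and the default
acquisition applies no photobleaching. An optional per-pixel boxcar
detrend (window = one segment, mean-preserving) strips components slower
than the segment; the boundary-frequency driver enables it.

## FRAP

`extract_recovery_curve()` measures the bleach-ROI mean per frame,
subtracts a background ROI (which must not overlap), optionally divides
by a background-subtracted reference ROI — double normalization, which
removes both acquisition bleaching and whole-pool depletion (bleaching a
body destroys part of the fluorescent pool; at equilibrium the reference
dims by the same factor) — and converts post-bleach frames to percentage
recovery anchored at the mean pre-bleach level (100) and the first
post-bleach frame (exactly 0). The bleach frame itself is excluded; time
zero is the first post-bleach frame. Non-uniform timestamps (1.3 s
pre-bleach spacing, then 5 s for 250 s) are carried explicitly.

`fit_recovery()` fits `R(t) = A (1 − e^{−kt})` by Levenberg–Marquardt
least squares (`minpack.lm`), the minimal saturating model for a single
effective exchange component; a two-component variant is available for
curves with distinct fast and slow pools (its maximum recovery is the
summed plateau). Optimizer failure falls back to the mean of the last
three points with `converged = FALSE`; plateaus above a 110 soft cap are
flagged, not clipped. `initial_rate()` is the origin-anchored regression
slope through the recovery at t = 5, 10, 15 s (`Σ tR / Σ t²`), equal to
R(15)/15 for linear data but noise-robust; the endpoint form is exposed
as an option, and off-grid curves are interpolated onto the 5-s grid.

The simulated FRAP experiment is designed to be *boundary-limited*: the
whole droplet (plus a 0.2 µm margin) is bleached, so recovery requires
influx across the rim and its rate constant is proportional to boundary
mobility. Geometry puts one 1-µm droplet in a 30-µm nucleus so the body
holds only ~8 % of the fluorescent pool (after double normalization the
plateau then reads `100·(1 − immobile_fraction)` to within a few points),
and the default permeabilities give a control rate constant near
0.025 s⁻¹: the control curve saturates within the 250-s protocol while
the five-fold slower stress curve does not — which is exactly how a
fixed-duration protocol shows a stress effect on both the maximum
recovery and the initial rate. The stress-comparison scenario omits the
reference ROI (single normalization, as is common practice), so mild
acquisition bleaching remains in those curves as it would in real data.

## Morphometry

Segmentation thresholds the protein channel *within the nucleus mask*
(Otsu on the within-nucleus histogram, 256 bins; a fixed threshold is
available), fills holes, labels 8-connected components (EBImage's
labeller is 4-connected, so the package carries its own two-pass
union-find), and discards objects below `min_area` (default 0.05 µm²).
Equivalent diameter is `2√(A/π)` — sizes are reported in µm² but classes
are defined in diameter. The printed class ranges share endpoints;
closed upper bounds are the tie-break (0.75 → I, 2.0 → II). Note that a
disc whose true diameter sits exactly on a class boundary can land on
either side after rasterization (sub-pixel area error); class assignments
are exact wherever the diameter is not within one pixel-equivalent of a
boundary. Fn/c and the RNA ratio are direct mean-intensity arithmetic
over caller-supplied masks, with typed errors for degenerate regions.

Illumination correction divides by a smooth field estimate and rescales
to preserve the global mean exactly. The field is estimated by
Gaussian-weighted local-*linear* smoothing (σ = width/8 pixels, applied
separably): unlike a plain Gaussian blur it reproduces linear shading
exactly at the image edges, where a truncated window would bias a ramp
and leave strong residual gradients.

## Group comparison

`compare_groups()` reproduces the normality-gated procedure: each group
is tested with the D'Agostino–Pearson omnibus K² (implemented from the
standard transformed-skewness and transformed-kurtosis formulas, since no
installed package provides it; verified against an independent reference
implementation). If all groups pass (p > 0.05), two groups get an
unpaired two-tailed equal-variance t-test and more get one-way ANOVA with
Tukey's HSD; if any fails, Mann–Whitney or Kruskal–Wallis with Dunn's
rank post-hoc under Holm adjustment (the non-parametric post-hoc is not
specified by convention; Dunn–Holm is the documented choice). Groups
below n = 8, where the omnibus test is undefined, route non-parametric
with a note. Pairwise marks use star tiers for the parametric branch and
hash tiers otherwise (0.05 / 0.01 / 0.001 / 0.0001).

## Problem sizes and determinism

The bundled experiments use the acquisition geometry of the protocols
they emulate: 1000-frame 64 × 64 movies with 2000 particles for moment
analysis (three seed-matched control/stress pairs for the fold-change),
55-frame FRAP protocols with 20 000 particles (three seeds per immobile
fraction), and 500 replicates for the type-I-error calibration. Every
entry point takes a seed and is bit-reproducible given identical inputs;
scenario summaries are identical across runs of the same `(name, seed)`.

## Known limitations

* The remodeling-event model is phenomenological; its rate/amplitude were
  chosen for a clean linear-response regime, not fitted to data.
* The frequency fold-change is a thresholded, saturating statistic: it
  recovers a five-fold mobility reduction to within ~±30 % (typically
  reading near 4), not exactly; see the remodeling-event section.
* Single-plane geometry: partition coefficients and plateau arithmetic
  are 2-D; absolute values will differ from 3-D measurements.
* CellProfiler-style declumping of touching bodies is not implemented;
  touching NBs merge into one object.
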