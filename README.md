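# nbdyn

Quantitative image analysis of liquid-like nuclear bodies (NBs) —
membrane-less, droplet-shaped protein condensates such as those formed by
GFP-tagged polyglutamine-expanded ataxin-1 — from confocal microscopy, with
a Brownian-dynamics synthetic-movie generator that provides ground truth
for every analysis step.

## Who it is for

Cell biologists and image analysts who quantify condensate behaviour from
confocal data and want the three standard read-outs of liquid-like
material state in one tested, scriptable package:

1. **Moment (variance/mean) mapping** — fluctuation imaging of coordinated
   protein mobility. For every pixel of an 80-frame segment (~10 s at
   121 ms/frame) the package computes the temporal mean, population
   variance, and their ratio (the index of dispersion). Pure photon shot
   noise gives a ratio of 1; coordinated multi-molecule movement — which
   concentrates at the droplet boundary — inflates it. Maps, high-ratio
   pixel frequencies (`ratio > 95th percentile` of a reference region) and
   axis profiles across a body reproduce the classic boundary-ring
   signature, and its loss where two bodies fuse.
2. **FRAP exchange dynamics** — recovery-curve extraction
   (`R(t) = 100·(F(t) − F_post)/(F_pre − F_post)` with background
   subtraction and optional double normalization), a single-exponential
   fit `R(t) = A·(1 − e^{−kt})` whose plateau `A` is the **maximum
   recovery %** (100 = fully mobile pool), and the **initial rate** in
   %/s, the origin-anchored slope through the recovery values at t = 5,
   10, 15 s (`Σ tᵢRᵢ / Σ tᵢ²`).
3. **Morphometry** — NB segmentation (Otsu within the nucleus, holes
   filled, 8-connected components), per-body area (µm²) and equivalent
   diameter `2√(A/π)`, size classes I (≤ 0.75 µm), II (0.75–2 µm),
   III (> 2 µm), total NB area per nucleus, the nucleus/cytoplasm
   intensity ratio Fn/c, and the background-corrected RNA ratio
   `(F_NB − F_bg)/(F_nonNB − F_bg)`.

Group comparisons use the field's normality-gated procedure: a
D'Agostino–Pearson omnibus test per group decides between t-test /
ANOVA + Tukey and Mann–Whitney / Kruskal–Wallis + Dunn–Holm.

The **simulator** (`simulate_droplet_movie()`, `simulate_frap_movie()`,
`simulate_fusion_movie()`, `render_static_nucleus()`) generates movies of
Brownian particles partitioning into liquid droplets with tunable boundary
permeability, interfacial remodeling, fusion, photobleaching protocols and
Poisson photon detection — so every analysis can be validated against
known ground truth, including recovering a five-fold reduction of boundary
mobility (the oxidative-stress phenotype) from the movies alone.

## Worked example

Simulate a control-condition acquisition of one nuclear body (1000 frames,
64 × 64 px, 13.5 µm field), map coordinated mobility, and measure the
boundary high-ratio frequency:

```r
library(nbdyn)

sim <- simulate_droplet_movie(seed = 1, record_trajectories = FALSE)
sim$movie
#> <nb_movie> 1000 frames of 64x64 px, t = [0, 121] s, counts in [0, 61]

freq <- boundary_frequency(sim)     # 80-frame segments, auto threshold
round(freq$overall, 3)
#> [1] 0.197
round(freq$threshold, 2)            # 95th pct of the droplet interior
#> [1] 1.57
```

A fifth of the rim-skirt pixels show a variance/mean ratio above the
interior's 95th percentile — the boundary ring of coordinated mobility.
Under the stress preset (boundary mobility × 0.2) the same measurement on
the seed-matched movie drops several-fold (about four-fold when pooled
over replicate seeds; the thresholded frequency slightly compresses the
five-fold ground truth — see the methods vignette):

```r
sim_s <- simulate_droplet_movie(seed = 1, preset = sim_preset("stress"),
                                record_trajectories = FALSE)
round(boundary_frequency(sim_s)$overall, 3)
#> [1] 0.057
```

FRAP on a simulated body with a 30 % immobile fraction recovers the
ground-truth mobile pool:

```r
frap <- simulate_frap_movie(seed = 7, immobile_fraction = 0.3)
analyse_frap_sim(frap, reference = TRUE)$fit
#> <nb_frap_fit> max recovery 74.4%, k = 0.01437 /s, initial rate 1.17 %/s
```

End-to-end scenario drivers bundle these experiments
(`run_scenario("fig2_boundary" | "fig2_fusion" | "fig4_stress_frap" |
"fig1_sizes", seed, out_dir)`), writing CSV tables and a JSON summary.
A thin CLI wraps the same functions:

```sh
Rscript inst/cli/nbdyn scenario --name fig1_sizes --seed 3 --out out/
```

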