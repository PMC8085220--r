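# pgcc — prompt-gamma Compton camera toolkit for proton range verification

`pgcc` is an R package for studying online range verification in proton
therapy with a two-plane Compton camera. It is aimed at medical-physics
researchers who want a self-contained, reproducible sandbox for the whole
verification chain:

1. **Simulate** labeled prompt-gamma coincidence events from a parametric
   source (discrete 4.439 / 6.129 / 2.223 MeV lines plus continuum, a
   Bragg-peaked longitudinal emission profile) and a configurable camera,
   including the background classes that contaminate real acquisitions
   (pair production + annihilation photons, wrong-ordered interactions,
   random coincidences, neutron-like deposits).
2. **Select** signal events with a small fully connected neural network
   (2 → 80 → 40 → 1, ReLU/ReLU/sigmoid, dropout 0.25, binary cross-entropy,
   0.5 decision cut) fed with the two measured plane energies only.
3. **Reconstruct** the four-dimensional (space × energy) emission image
   with spectral list-mode MLEM: every event is backprojected once per
   candidate energy bin as a Compton cone

   cos θ = 1 − mec² (1/(E0−E1) − 1/E0),

   modelled as a dense ray set traced through the voxel grid by compiled
   code, and the image is updated by
   λj ← (λj/sj) Σi aij / (Σk aik λk), with a 3×3×1×3 median filter between
   iterations.
4. **Assess** the 4.4 MeV image (4.3–4.5 MeV integral): longitudinal
   profiles, maximum / R80 / R50 distal fall-off positions with linear
   interpolation, transverse FWHM, contrast-to-noise ratio
   CNR = |S − μ|/σ, Gaussian spectral-peak fits, and range-shift estimates
   between acquisitions.

The methods vignette (`vignettes/range-verification.Rmd`) documents the
model, its assumptions, every tunable parameter, and the design decisions.

## Worked example

Train the selector on one synthetic acquisition and evaluate it on a
held-out one:

```r
library(pgcc)
geom   <- camera_geometry()
src    <- source_model()
events <- generate_dataset(20000, geometry = geom, source = src, seed = 1)
model  <- train_selector(events, seed = 2)

heldout  <- generate_dataset(20000, geometry = geom, source = src, seed = 3)
accepted <- select_events(model, heldout)
selection_metrics(heldout, accepted)
#> recall 87.9% | precision 35.1% | signal % 7.6 -> 35.1 (relative increase 362.2%)
```

The held-out acquisition contains 7.6% true signal; after the network's
0.5 cut the accepted subset is 35.1% signal while 87.9% of all true signal
events are kept — the enrichment that makes the 4.4 MeV line usable for
imaging downstream.

Reconstruct and assess the accepted events:

```r
grid  <- fov_grid()                      # 101 x 101 x 1 voxels of 3 mm,
                                         # 92 bins of 0.1 MeV (0.8..9.9 MeV)
image <- reconstruct(accepted, grid, geometry = geom, iterations = 50)
slice <- integrate_energy(image, 4.3, 4.5)
prof  <- longitudinal_profile(slice, grid)
range_metrics(prof)                      # max / R80 / R50 along the beam, mm
```

A complete simulate → train → select → reconstruct → assess chain, driven
by one YAML configuration and one seed, is available as `run_pipeline()`
and as the command-line tool installed at `inst/cli/pgcc`
(`pgcc pipeline --config demo.yaml --seed 7`).

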