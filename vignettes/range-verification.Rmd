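---
title: "Prompt-gamma range verification with a two-plane Compton camera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prompt-gamma range verification with a two-plane Compton camera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgcc)
```

## The problem

Proton therapy concentrates dose at the Bragg peak, which makes treatments
exquisitely sensitive to range errors. Prompt gamma (PG) photons are emitted
within nanoseconds of nuclear interactions along the beam path; the emission
profile of the 4.439 MeV carbon de-excitation line drops sharply near the end
of range, so its distal fall-off tracks the beam range. A Compton camera
images these photons without mechanical collimation: a photon Compton
scatters in a first detector plane (scatterer, deposit $E_1$) and interacts
again in a second plane (absorber, deposit $E_2$); if the initial energy
$E_0$ were known, the origin would be constrained to a cone with apex at the
scatter position, axis along the scattered-photon path, and half-angle
$\theta$ from the Compton formula

$$\cos\theta = 1 - m_ec^2\left(\frac{1}{E_0 - E_1} - \frac{1}{E_0}\right).$$

The PG spectrum is polychromatic and the absorber does not always stop the
scattered photon, so $E_0$ is unknown per event. The *spectral*
reconstruction used here treats the emission energy as a fourth image
dimension: every event is backprojected once per candidate energy bin, and a
list-mode MLEM estimates the non-negative emission intensity
$\lambda_j$ on the 4D grid:

$$\lambda_j \leftarrow \frac{\lambda_j}{s_j}\sum_i
  \frac{a_{ij}}{\sum_k a_{ik}\lambda_k},$$

with $a_{ij}$ the system weight of event $i$ at 4D voxel $j$ and $s_j$ the
detection sensitivity. Between iterations a $3\times3\times1\times3$ median
filter regularizes the estimate. Range information is extracted from the
image integrated over 4.3–4.5 MeV: longitudinal profiles along the beam,
the maximum position, and the depths R80 / R50 where the profile falls to
80% / 50% of its maximum on the distal edge.

Because high-intensity beams flood the camera with background (pair
production followed by annihilation-photon detection, wrong-ordered
interactions, random coincidences, neutron-induced deposits), a small fully
connected network (2 → 80 → 40 → 1, ReLU/ReLU/sigmoid, 25% dropout after the
first hidden layer, binary cross-entropy, 0.5 decision cut) classifies
events as signal or background from the two measured energies alone before
reconstruction.

## What the simulator emulates — and what it does not

`generate_dataset()` is a parametric stand-in for a full Monte-Carlo
transport simulation of a 150 MeV proton beam on a PMMA target:

* **Longitudinal emission profile**: monotone build-up
  $b + (1-b)(u/L)^p$ from the target entrance to the peak at
  $L = 133.5$ mm (the calculated Bragg-peak depth for this beam/target),
  followed by a Gaussian distal fall-off of scale 6 mm. Defaults
  $b = 0.05$, $p = 3$ concentrate the emission near the end of range. A
  flatter entrance plateau (as real PG profiles have) is supported by the
  parameters, but then the analysis field of view must cover the whole
  target, as in the full-scale configuration: activity emitted outside the
  FoV is otherwise piled onto the FoV boundary by MLEM.
* **Spectrum**: discrete lines at 4.439 (carbon), 6.129 (oxygen) and
  2.223 MeV (neutron capture on hydrogen) plus a decaying continuum;
  weights 0.45/0.10/0.15 with 0.30 continuum. Spatial and spectral
  coordinates are sampled independently — the spatial decorrelation of the
  2.2 MeV neutron-capture line seen in measurements is *not* modelled.
* **Signal transport**: exact Compton kinematics (Klein–Nishina angle,
  energy sharing), solid-angle flux through the scatterer face, absorber
  propagation. Unblurred events satisfy the cone-containment identity to
  machine precision, the ground-truth link the reconstructor exploits.
* **Detector response**: 5% FWHM energy resolution at 0.511 MeV scaling as
  $1/\sqrt{E}$, 2 mm in-plane position blur, full absorption of the
  scattered photon with probability `p_photopeak` (default 0.5), otherwise
  a uniform partial deposit.
* **Backgrounds**: pair production + annihilation photon ($E_2 = 0.511$),
  wrong-ordered records (plane energies swapped), random coincidences and
  neutron-like broad deposits, at a 7.6% signal prevalence among
  threshold-passing coincidences (750 keV on $E_1+E_2$). Deposit positions
  of background classes are beam-correlated (aimed from sampled emission
  points), as beam-induced background is in reality. Default class split
  0.65/0.25/0.05/0.05: the pair class dominates, and diffuse
  neutron/random clutter is minor — consistent with post-selection spectra
  in which the discrete lines remain clearly visible.

Passing tests on these data demonstrate the *algorithms* — kinematics,
selection, reconstruction, assessment — under controlled conditions; they do
not certify performance on data from full particle transport or a real
detector, whose background phase space is richer than the four parametric
classes.

## The system model of the reconstructor

`backproject_events()` models each cone as a dense set of rays (default 180,
one per 2° of azimuth) and accumulates exact voxel chord lengths with a
compiled Siddon-style tracer. Three deliberate weighting choices make the
discretized backprojection a consistent likelihood model:

* **Surface measure and physics weights.** Each chord is multiplied by
  $\sin\theta$ (converting the ray bundle to the cone-surface measure) and
  by the Klein–Nishina density at the candidate angle. No radial weight is
  applied: the cone-surface element grows as $r$, the Jacobian of the
  $E_1$ constraint contributes another $r$, and the solid-angle flux toward
  the scatterer falls as $1/r^2$ — the factors cancel. With a mismatched
  radial measure, reconstructed activity drifts systematically along the
  camera viewing axis (the soft direction of a single-view Compton camera).
* **Absorber response.** With probability `p_peak` the absorber records the
  full scattered energy, making $E_0 = E_1 + E_2$: that delta component is
  represented by one cone at exactly $E_1+E_2$, placed in its energy bin
  with a Gaussian weight under the energy resolution. Partial deposits
  spread the remaining probability over all higher candidate energies.
  This response is what disambiguates distance from energy for a
  small-aperture camera; a hard threshold instead of the Gaussian weight
  biases candidates upward for upward-blurred events.
* **Bin integration.** Each bin's cone set is integrated over `n_sub = 3`
  sub-energies across the bin width, so emission lines that do not coincide
  with a bin center still backproject through their true origin.

The sensitivity $s_j$ defaults to a *flood* estimate: emissions drawn
uniformly over the 4D FoV are pushed through the simulator and backprojected
with the same discretized operator; the summed backprojection, box-smoothed
(the true field is smooth; the raw estimate carries ~30% Monte-Carlo noise
per voxel that would otherwise imprint a static speckle pattern) and floored
at 10% of its maximum (bounding noise amplification at the FoV periphery),
is the sensitivity. The classical voxel-center detected-fraction estimate
(`method = "montecarlo"`) and a uniform fallback are also provided.

## Numerical conventions

* Energy bins: centers at `energy_min + 0.1 k`; the default axis has 92
  centers from 0.8 to 9.9 MeV, each bin spanning ±0.05 MeV.
* The median filter runs *between* successive MLEM iterations (after every
  update except the last); `median_filter_4d()` can be applied once more
  when the assessed image should be the regularized estimate (the
  range-shift study does). Borders use truncated windows. A single-line
  noiseless source concentrates in one energy bin, which a 3-wide energy
  median annihilates — use `use_filter = FALSE` or a `c(3,3,1,1)` window
  for such data.
* R80/R50 are located on the falling edge after the global maximum at the
  *most distal* downward crossing of the threshold, by linear interpolation
  between the bracketing voxels. On a clean single-peak profile this equals
  the textbook definition; on noisy profiles with local peaks before the
  distal edge it keeps tracking the end of range — the same robustness
  pattern reported for R80 versus the maximum position in range-verification
  experiments. The maximum uses the first (most proximal) voxel on ties.
* A single-voxel transverse spike reports an FWHM of one voxel width
  (crossings clamped at the half-voxel flanks).
* Events whose backprojection never touches the grid are dropped with a
  warning before MLEM; events with zero forward projection are dropped
  inside the update, never raised as errors.
* MLEM initializes at 1 everywhere; all accumulation orders are fixed, so
  reconstruction is bit-for-bit reproducible from its inputs.
* The selector trains with class-balanced binary cross-entropy (option
  `balance_classes`). At 7.6% prevalence an unweighted network collapses to
  rejecting everything; balanced weights turn the 0.5 cut into a
  likelihood-ratio test, the operating regime in which a sizeable fraction
  of events is accepted while the signal is enriched.
* One global seed fans out to per-stage seeds as
  `(seed * 7919 + stage) mod (2^31 - 1)`, so stages can be re-run in
  isolation.

## The reduced-scale range-shift study

`range_shift_study()` packages the end-to-end verification experiment at a
desk scale: two acquisitions differing only by a +3 mm source translation,
5000 selected events each, reconstructed on a 41 × 41 × 1 grid of 3 mm
voxels with 0.1 MeV bins over 3.0–6.0 MeV, 25 MLEM iterations and 90 rays
per cone; the recovered displacement is the R80 difference of the 4.4 MeV
longitudinal profiles. Design choices specific to this study:

* Detector planes of 100 × 100 mm — the plane size used in the simulation
  study that trains the selector (enlarged relative to the 25.8 mm
  experimental crystals to gain statistics). The larger aperture also
  decoheres the mirror ghost a small camera folds across its axis.
* Camera axis over the expected distal fall-off; analysis grid centered
  between build-up and fall-off; profiles integrated over a 60 mm
  transverse slice, matching this camera's simulated lateral spread (the
  3 cm experimental choice was matched to a much narrower spread);
  profiles analyzed inside a corridor around the planned range
  (−40 mm to +55 mm), covering the displacement span a verification
  system must handle while excluding the FoV periphery.

**Known limitation — statistics at reduced scale.** With 5000 selected
events at 7.6% prevalence and ~20% post-selection precision, roughly 1000
true signal events form each image — about forty times fewer than in the
full-scale simulation study this experiment miniaturizes. In a control
with 3000 pure signal events per acquisition the recovered displacement
for a +3 mm shift is 2.8 ± 2.3 mm with the correct sign in 8 of 8 seeds,
so the chain does track millimetre shifts once the signal statistics are
adequate. At the full mixed-background study scale, however, the
reconstructed 4.4 MeV profile is only about twice as high at the peak as
the residual background plateau, the profile maximum occasionally flips
to a background structure, and the R80 difference across seeds 1–8 is
1.3, 69.5, 61.4, −60.6, 77.5, −8.4, 16.2, 7.1 mm (sign correct in 6 of 8,
within one voxel of +3 mm in 1 of 8). One-voxel shift recovery at this
event budget is therefore not statistically reliable; it requires
full-scale statistics (tens of thousands of selected events), exactly as
in the original experiment, whose selected dataset was roughly forty
times larger. The study function is still the package's end-to-end
demonstration and the basis of the reproducibility script; its single-run
output must be read against the dispersion above.

## Problem sizes used by the tests

Unit tests run on grids from 1 × 1 × 1 to 41 × 41 × 1 voxels with a few
dozen to a few hundred events; the sampler goodness-of-fit checks use
10^5 draws; the end-to-end point-source check uses 500 noiseless events on
the reduced grid; the shift study uses the configuration above. These sizes
are the package's chosen validation scale; all expected values are computed
by independent oracles (closed forms, numeric integration, brute-force cone
sampling) rather than recorded from the implementation.
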