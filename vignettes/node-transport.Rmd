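---
title: "Quantifying organelle transport at the node of Ranvier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying organelle transport at the node of Ranvier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodetrans)
library(dplyr)
```

## The problem

Myelinated peripheral axons are interrupted every few hundred micrometres
by nodes of Ranvier (NoR): short unmyelinated constrictions where the axon
narrows, the cytoskeleton reorganizes, and action potentials regenerate.
Intravital time-lapse microscopy of motor axons shows that fast axonal
cargoes — retrogradely transported signaling endosomes and bidirectionally
moving mitochondria — change their behaviour as they transit the node:
they slow down, pause more often, and accumulate just distal to the
constriction. `nodetrans` turns the measurements behind those observations
into a reusable, tested pipeline: node-centered kinematics, mitochondrial
directionality and flux, fluorescence accumulation profiles, and nodal
morphometry, together with a stochastic track generator that carries its
own ground truth so every stage can be validated by parameter recovery.

## The kinematic model

The unit of analysis is the *frame-to-frame step*. Tracks arrive as 2D
spot sequences $(x_i, y_i, t_i)$ from an upstream tracker; an axon
centerline polyline with a marked node center maps every spot to a signed
axial coordinate $s$ (positive distal, toward the muscle; negative
proximal, toward the soma; anterograde movement increases $s$). For each
consecutive pair of spots,

* apparent speed $= \sqrt{\Delta x^2 + \Delta y^2} / \Delta t$ (the full
  2D displacement — tracking is 2D),
* location $= (s_i + s_{i+1})/2$, the midpoint axial position,
* a **pause** is a step with apparent speed $\le$ 0.1 µm/s (a threshold
  that absorbs breathing/pulsing artefacts in vivo).

Steps are binned every 2 µm across an 80 µm window centered on the node
and partitioned into the proximal internode ($[-40, -2)$ µm), the nodal
constriction ($[-2, +2]$ µm, the mean 4 µm nodal length), and the distal
internode ($(+2, +40]$ µm). Per location the pipeline reports

* **mean moving velocity**: the mean apparent speed over non-pause steps
  (undefined, not zero, where a location has no moving steps), and
* **pause relative frequency**: pauses divided by all steps in that
  location — the per-location analogue of "time paused (%)". The
  alternative normalization (a location's share of all pauses) is
  available via `pause_freq_mode = "share_of_pauses"`.

Track-level filters mirror standard practice: terminal pause runs of
$\ge$ 10 consecutive steps are trimmed from either end (iteratively, so a
newly exposed terminal run is also removed); a track qualifies only if it
retains a run of $\ge$ 10 consecutive moving steps; and each axon should
contribute $\ge$ 20 trackable organelles ($\ge$ 10 for retrogradely moving
mitochondria) — enforced as a warning by default, since requirements and
enforcement mechanics are distinct concerns.

Mitochondrial direction is classified per track after trimming: a track
with no qualifying moving run, or with absolute net axial displacement
below 2 µm (one bin width), is *stationary*; otherwise the sign of the
summed axial displacement over moving steps decides *anterograde* versus
*retrograde*, with the majority step sign as tie-break and a stationary
fallback (with warning) if even that ties. Flux counts distinct organelles
— not steps — per subdomain and direction, normalized to video minutes;
pooling takes the mean of the three subdomain fluxes per axon, then the
mean across axons. Reporting everywhere follows the hierarchical
convention: per-axon means first, then unweighted means of axon means per
animal (`aggregate_hierarchy()`).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pause_speed_threshold` | 0.1 | µm/s | separates motor-driven steps from jitter and physiological artefact |
| `min_consecutive_moving_frames` | 10 | steps | excludes organelles never in processive transport |
| `terminal_pause_min_frames` | 10 | steps | removes docking/undocking tails that are not transit behaviour |
| `window_half_width` / `bin_width` | 40 / 2 | µm | 80 µm node-centered window, 40 bins |
| `internode_length` / `node_length` | 38 / 4 | µm | the 38/4/38 partition; 4 µm is the mean nodal constriction length |
| `max_gap_frames` | 2 | frames | a 2-frame gap becomes one spanning step (`is_gap`); larger gaps split the track |
| `stationary_net_threshold` | 2 | µm | secondary stationarity criterion, one bin width |
| `max_lateral_um` (projection) | 10 | µm | spots farther from the centerline are presumed mis-assigned |

## What the generator emulates — and what it does not

`simulate_tracks()` implements a state-switching transport model: at each
frame an organelle either pauses (zero displacement) with a probability
set by the region of its current position, or advances along the axis by
`direction × speed × Δt`, with speed drawn from a truncated normal whose
mean is region-dependent. Presets encode the study conditions: retrograde
endosomes imaged at 0.5 s frame intervals with regional speed means
2.40 / 1.25 / 2.10 µm/s (proximal / node / distal, SD 0.25) and pause
probabilities 0.042 / 0.30 / 0.099; a soleus variant (2.41 / 1.30 / 2.00);
mitochondria at 1.7 s intervals, 76% anterograde, anterograde speeds
0.500 / 0.360 / 0.456 and retrograde 0.500 / 0.380 / 0.494 µm/s (SD 0.05),
more anterograde pausing at the node (0.20 vs 0.12); stationary
mitochondria (mean length 1.8 µm vs 1.1 µm motile) clustered
$\mathcal{N}(+3.75, 2^2)$ µm distal to the node. These constants were
chosen once so that closed-form ratios of programmed parameters equal the
effect sizes the pipeline should recover; `null_uniform` is the negative
control with identical parameters everywhere. Tracks start uniformly in
[−45, +45] µm on a straight 100 µm axon (node at its middle, 5 animals ×
3 axons by default, i.e. 20 organelles per axon at the 300-track default)
and stop when they leave ±48 µm. Localization noise is isotropic Gaussian,
SD 0.01 µm — intentionally optimistic, so that at the 0.1 µm/s threshold
pause detection is essentially unconfounded (the generator asserts at run
time that under 1% of true pauses read as moving).

The default pause process is i.i.d. Bernoulli per step, which makes the
programmed probability exactly the expected pause-step fraction and keeps
recovery targets analytic; a two-state Markov variant
(`pause_model = "run_length"`) produces geometrically distributed pause
runs with the same stationary fraction for more realistic run structure.

Deliberately not modelled: image formation (no PSF or photophysics — the
generator emits tracker output, not movies), curved "S-shaped" or
circular trajectories near the node (only optional lateral funneling
bounded by the local axon radius), drift, fission/fusion, and
inter-organelle interactions. Passing recovery tests therefore
demonstrates that the pipeline measures what the model programs — it
cannot certify behaviour on artefacts these simplifications exclude
(tracking errors, anisotropic noise, node-adjacent trajectory geometry).

Two systematic effects are worth knowing about. First, the generator
draws a step's speed from the region of its *starting* position while the
pipeline assigns the step to the region of its *midpoint*; steps
straddling a boundary therefore blur the regional contrast, and recovered
nodal slowdowns sit a couple of percentage points below the programmed
ratios — an inherent property of binned step statistics at a 4 µm node,
not an estimator bug. Second, because speed is 2D while location is
axial, any lateral motion (e.g. funneling) inflates apparent speeds
slightly; with funneling off (the preset default) the inflation from
localization noise alone is negligible.

## Accumulation profiles

`simulate_profiles()` emits
$F(s) = (b + B\,(1 + A e^{-(s - c)^2 / 2\sigma^2}))\,\eta$, with baseline
$B = 1$, amplitude $A = 0.5$, center $c = +3.75$ µm, $\sigma = 2$ µm, an
additive instrument pedestal $b$ (default 0.5), and unit-mean lognormal
noise $\eta$ (SD 0.1), sampled every 0.5 µm over ±40 µm. The analysis
chain is background subtraction, normalization to relative fluorescence,
averaging across axons, then peak metrics (peak location on the distal
side and peak over proximal-internode mean).

Background choice matters. When a measured background exists — as in real
workflows, where it is taken from an off-axon image region, and in the
generator, which records its pedestal — `subtract_background(method =
"value")` removes exactly the additive offset and the expected
peak-over-proximal ratio is the programmed $1 + A$. The percentile
fallback (default 10th percentile of the profile itself) exists for data
without any background measurement, but on a profile that contains signal
at every sample it necessarily removes part of the axonal baseline and
inflates relative metrics; it should be read as a conservative
"structure-above-floor" view, not an absolute calibration. Peak
extraction applies a 3-sample running mean (1 µm) before the argmax:
taking the maximum of a noisy curve is biased upward, and this light
smoothing removes most of that selection bias while attenuating a
several-µm-wide accumulation by well under 1%.

## Morphometry

`detect_constriction()` operationalizes what is a by-eye measurement at
the microscope: node center = diameter minimum (ties resolved toward the
window midpoint), internodal diameter = mean diameter $\ge$ 10 µm from
the center, and node length = width of the contiguous region where the
diameter stays below the half-depth level
$d_{\min} + 0.5\,(d_{inter} - d_{\min})$, with linear interpolation of
the two crossings for sub-grid precision. The 50% fraction is
configurable; a relative depth under 10% is reported as "no
constriction" rather than a spurious fit. The generator's counterpart
builds raised-cosine flanks whose full width at half depth equals the
programmed node length exactly, so the noise-free round trip is analytic.

## Numerical choices and degenerate inputs

* Projection onto the centerline searches all polyline segments, clamping
  to segment ends; exact ties go to the lower arclength, making the map
  deterministic. Flipping the distal sign negates $s$ exactly and swaps
  direction labels exactly.
* Bins are half-open $[e, e + 2)$ with edges aligned at 0; the closing
  +40 µm edge belongs to the last bin. The nodal subdomain is closed on
  both sides, so a step at exactly ±2 µm is nodal.
* A pause step has zero displacement, so its midpoint equals its
  position; pauses never blur across bins.
* Empty locations yield `NA` velocities, never 0; all-pause tracks trim
  to empty and are rejected with a reason code, not an error.
* Truncated-normal speed draws use the inverse-CDF method (exact, no
  rejection loop); truncation at 0.15 µm/s keeps every moving step above
  the pause threshold by construction.
* All randomness flows from the single config seed; identical
  configurations reproduce datasets bit-for-bit.

## Problem sizes

The recovery checks in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` use the preset defaults: 300 tracks per dataset
across 5 seeds for each kinematic preset (150 frames at 0.5 s for
endosomes, 200 at 1.7 s for mitochondria), 20 noisy profiles for the
accumulation preset, and 10 noisy diameter profiles for morphometry —
sizes at which regional means are stable to well under the tolerances
being checked, while a full run stays around a minute.

## Limitations

* The pipeline quantifies; it does not infer. Group comparisons (ANOVA
  and post hoc tests in the original workflow) are out of scope; only
  descriptive aggregation and Pearson correlation are provided.
* Whether published velocities derive from 2D or axis-projected
  displacement, how bins were aligned, and which background estimator was
  used are unstated in the source workflow; the choices here (2D speed,
  edge-aligned bins, measured-background subtraction with a percentile
  fallback) are documented conventions, not recovered facts.
* The TrackMate reader ingests a minimal subset (positions, frames, track
  edges) and ignores everything else, including gap-closing metadata
  beyond what the frame indices imply.
* No image processing: spot detection, tracking and kymograph extraction
  happen upstream.
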