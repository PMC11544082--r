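# nodetrans

Node-centered quantification of in vivo axonal organelle transport.

Nodes of Ranvier (NoR) are the short unmyelinated constrictions of
myelinated axons. As fast axonal cargoes — retrogradely transported
signaling endosomes and bidirectionally moving mitochondria — transit the
node in peripheral motor axons, their transport changes measurably: they
slow down, pause more often, and pile up just distal to the constriction.
`nodetrans` is an R package for researchers analysing intravital
time-lapse tracking data around the NoR. It implements:

- **Track I/O and geometry** — a plain CSV track dialect, a reader for a
  TrackMate-style XML subset, and projection of 2D spots onto an axon
  centerline giving each spot a signed node-centered axial position *s*
  (positive = distal).
- **Kinematics** — frame-to-frame step records; pause detection
  (apparent speed ≤ 0.1 µm/s); trimming of terminal pause runs (≥ 10
  steps); track qualification (≥ 10 consecutive moving steps); 2-µm
  binning across an 80-µm node-centered window split 38/4/38 µm into
  proximal internode, nodal constriction and distal internode; mean
  moving velocity (pause steps excluded) and pause relative frequency
  (pauses / steps) per bin and subdomain; Pearson speed–diameter
  correlation.
- **Directionality, flux and length** — anterograde / retrograde /
  stationary classification from net axial displacement, per-subdomain
  counts of distinct moving mitochondria, per-minute flux, and mean
  organelle length by motility class and region.
- **Accumulation profiles** — background subtraction, relative
  normalization, mirrored proximal/distal comparison and distal peak
  metrics of fluorescence line profiles.
- **Morphometry** — summaries of manual diameter/length measurements and
  a half-depth constriction detector for diameter profiles.
- **Synthetic data** — a seeded state-switching transport simulator with
  named presets whose programmed parameter ratios equal the effect sizes
  the pipeline should recover, carrying full ground truth.

The core kinematic quantities, per axonal location *L* (bin or
subdomain), are

```
mean moving velocity(L)      = mean( speed | step in L, not a pause )
pause relative frequency(L)  = #pauses in L / #steps in L
```

with a pause defined as a frame-to-frame interval whose 2D speed is
≤ 0.1 µm/s, and effect sizes reported as percent contrasts such as
`100 × (1 − v_node / v_proximal)`.

## Worked example

Simulate a study-calibrated dataset of retrogradely transported
endosomes and run the full node-centered analysis:

```r
library(nodetrans)

sim <- simulate_tracks(generator_config("endosome_paper", seed = 1))
nk  <- node_kinematics(sim$tracks, sim$geometry)
nk
#> <node_kinematics> 304 tracks (269 qualified), 13144 in-window steps
#> # A tibble: 3 × 5
#>   subdomain n_steps n_pauses mean_moving_velocity pause_relative_frequency
#>   <fct>       <int>    <int>                <dbl>                    <dbl>
#> 1 proximal     7208      294                 2.39                   0.0408
#> 2 center       1243      388                 1.31                   0.312
#> 3 distal       2926      315                 2.10                   0.108
```

Endosomes move at ~2.4 µm/s through the proximal internode but only
~1.3 µm/s inside the nodal constriction, where they also pause about
seven times more often. `glance()` turns those subdomain means into the
standard percent contrasts:

```r
glance(nk)[, 4:8]
#> velocity_node_vs_proximal_pct           44.9
#> velocity_node_vs_distal_pct             37.6
#> velocity_proximal_vs_distal_excess_pct  13.4
#> pause_proximal_vs_node_reduction_pct    86.9
#> pause_distal_vs_node_reduction_pct      65.5
```

i.e. this dataset shows a ~45% nodal slowdown relative to the proximal
internode, ~14% faster proximal than distal transport, and ~87% / ~66%
less pausing in the internodes than at the node. `autoplot(nk)` draws the
per-bin velocity/pausing profile; `tidy(nk, by = "bin")` returns it as a
table. The same objects feed the mitochondrial stages
(`classify_motility()`, `count_directional_movements()`,
`flux_per_minute()`, `length_summary()`), and `run_pipeline()` provides a
file-based front end (`simulate`, `kinematics`, `flux`, `profile`,
`morphometry`, `report`) that writes TSV outputs plus a run manifest.

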