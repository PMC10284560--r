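# svtether

Quantitative cryo-electron tomography morphometrics of synaptic vesicle
tethering at the presynaptic active zone.

Synaptic vesicles (SVs) are recruited to and held at the active-zone (AZ)
membrane by short protein bridges that are directly visible in cryo-ET
volumes: **tethers** (SV ↔ plasma membrane) and **connectors** (SV ↔ SV).
Their geometry discriminates functional vesicle states — SVs < 5 nm from
the AZ with short tethers (a SNAP25-dependent state), 5–10 nm
(intermediate), and ≥ 10 nm (Munc13-independent). svtether is for
structural neurobiologists who have reconstructed, segmented-membrane
tomogram volumes (or none at all — a ground-truthed phantom generator is
built in) and want reproducible, threshold-free bridge detection and the
standard statistical comparisons on top.

## What it computes

* **Hierarchical connectivity segmentation.** For an increasing threshold
  series $t_1<\dots<t_K$, foreground at $t$ is the set of analysis-region
  voxels with density $\le t$ (structure-low contrast); 26-connected
  components linking exactly {one SV + AZ membrane} are tethers, exactly
  {two SVs} connectors. Each bridge is reported as the component at the
  *lowest* threshold at which it links its boundaries — its "core" — so
  the detection has no per-structure free parameter.
* **Morphometrics.** SV distance to the AZ membrane
  $d=\max(0, d_{\min}-1\,\text{voxel})$ (edge-to-edge, ± 1 voxel);
  geodesic bridge length $L$ through the segment's voxels (26-neighbour
  steps, weights $1,\sqrt2,\sqrt3$), so curvature counts; tether classes
  < 6 / 6–12 / 12–24 nm; tether and connector counts per vesicle;
  1-voxel layer occupancy profiles with proximal/intermediate/distal
  zones at 45 / 75 / 250 nm; AZ surface area and proximal-SV surface
  concentration per µm²; atomic-model span measurement and a geometric
  tether-accommodation screen.
* **Statistics.** Planned, orthogonal pairwise comparisons only:
  Student's *t* (Welch optional), Kruskal–Wallis (kept for two groups),
  Pearson χ² without continuity correction for frequencies, Pearson
  correlation; SEM between synapse means for fractions; empirical CDFs
  with inflection points as midpoints of steep-increase regions; missing-
  wedge orientation equalization with a logged removal order.
* **Phantoms.** MRC-writable synthetic volumes (membrane slab, spherical
  vesicles at prescribed AZ distances, curved tube bridges, Gaussian
  noise, missing-wedge filter) with exact ground truth, so every stage is
  testable offline.

## Worked example

Generate a noiseless phantom with three vesicles at 3 / 7 / 14 nm, one
straight tether each and two connectors, then run the full per-synapse
analysis:

```r
library(svtether)

spec <- phantom_spec(
  volume_shape = c(64, 64, 64), voxel_size_nm = 1.4,
  vesicles = tibble::tibble(x_nm = c(18, 45, 72), y_nm = 45,
                            radius_nm = 12, distance_nm = c(3, 7, 14)),
  tethers = tibble::tibble(vesicle = 1:3, shape = "straight",
                           az_dx_nm = 0, az_dy_nm = 0, bulge_axis = "x",
                           radius_nm = 2.1),
  connectors = tibble::tibble(vesicle_a = c(1, 2), vesicle_b = c(2, 3),
                              radius_nm = 2.1),
  noise_sigma = 0)
ph <- generate_phantom(spec)
res <- run_synapse(ph$density, ph$labels,
                   run_config(schedule_absolute = c(0.25, 0.5, 0.75)),
                   synapse_id = "phantom1")
res$vesicles[, c("vesicle_id", "distance_nm", "n_tethers", "n_connectors", "state")]
#> # A tibble: 3 × 5
#>   vesicle_id distance_nm n_tethers n_connectors state
#>        <int>       <dbl>     <int>        <int> <chr>
#> 1         10         4.2         1            1 SNAP25-dependent
#> 2         11         8.4         1            2 intermediate
#> 3         12        15.4         1            1 Munc13-independent
res$segments[, c("segment_id", "kind", "length_nm", "tether_class")]
#> # A tibble: 5 × 4
#>   segment_id kind      length_nm tether_class
#>        <int> <chr>         <dbl> <chr>
#> 1          1 tether          2.8 short
#> 2          2 tether          7   intermediate
#> 3          3 tether         14   long
#> 4          4 connector       2.8 <NA>
#> 5          5 connector       1.4 <NA>
```

The three planted distances are recovered within one voxel (+1.2 nm
discretization bias on a 1.4 nm grid) and land in the expected states;
each tether's geodesic length matches its planted span within a voxel,
and classes follow the < 6 / 6–12 / 12–24 nm convention. The synapse
summary adds the AZ area (6766 nm² here, the planted patch being
80.6 × 80.6 nm) and the proximal-SV surface concentration (443 per µm²
for 3 vesicles). `run_study()` pools many such synapses across
conditions, equalizes orientations, and runs the planned comparisons;
`tidy()`/`glance()` and `autoplot()` give tibbles and ggplots of every
result type.

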