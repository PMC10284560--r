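---
title: "Methods: quantifying synaptic vesicle tethering in cryo-ET volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying synaptic vesicle tethering in cryo-ET volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svtether)
```

## The problem

Synaptic vesicles (SVs) are held near the presynaptic active zone (AZ) by
short pleomorphic protein bridges. In cryo-electron tomograms these appear
as faint, curved rod-like densities: *tethers* link an SV to the AZ
membrane, *connectors* link two SVs. Their lengths, counts and the SV
distances to the AZ membrane discriminate functional vesicle states — an
SNAP25-dependent state (< 5 nm, short tethers), an intermediate state
(5–10 nm) and a Munc13-independent state (≥ 10 nm) — so a pipeline that
measures them reproducibly, without per-structure manual thresholding, is
the core analysis instrument. svtether implements that pipeline end to
end: segmentation, morphometry, statistics, and a ground-truthed phantom
generator that makes every stage testable without tomogram data.

## Hierarchical connectivity segmentation

Bridges are too variable for template matching, and any single global
threshold either merges them into noise or erases them. The detector
instead scans an increasing series of grayscale thresholds
$t_1 < \dots < t_K$. At each $t$, the foreground is the set of analysis-
region voxels with density $\le t$ (cryo-ET contrast: structure is dark),
and its 26-connected components are computed. A component is *valid* when
its boundary-contact signature — the set of labelled objects its voxels
touch by 26-adjacency — is `{one SV, AZ membrane}` (tether) or
`{two SVs}` (connector). Every reported segment is the component at the
**lowest** threshold at which it is valid, its *core*; a component at a
higher threshold that contains an already-reported core is represented by
that core alone. Cores are therefore mutually disjoint, and the procedure
has no per-structure free parameter.

Components touching three or more boundaries, a single boundary, or only
non-AZ membrane are rejected, not split; splitting would require a
watershed-type decision that the discrete tether/connector definitions do
not license.

The default schedule is 24 evenly spaced quantiles of the region's
density between probabilities 0.02 and 0.5, which is invariant to linear
contrast changes in real, noisy volumes. Noise-free phantoms have nearly
binary densities whose quantiles collapse, so tests on them use explicit
absolute thresholds; both rules are exposed in `threshold_schedule()` and
recorded in the run manifest.

The implementation (component labelling, contact extraction, distance
transform, geodesics) is compiled code under `src/`; the test suite
checks it against an exhaustive per-threshold oracle built independently
on igraph, on grids small enough to enumerate.

## Measurement definitions

All voxel coordinates are 1-based R array indices in axis order
(x, y, z), z being the beam axis; nanometres appear only in reported
quantities. Working in native array indices (rather than a 0-based
(z, y, x) convention) keeps every subscript directly usable in R and
confines unit conversion to the reporting layer.

**SV distance to the AZ membrane** $d$: the minimal voxel-centre to
voxel-centre distance between SV and AZ-membrane voxels, minus one voxel,
clamped at zero. The subtraction makes face-adjacent surfaces score 0 and
approximates edge-to-edge distance between surfaces; with ≈ 1.4–1.8 nm
voxels, sub-voxel refinement is not meaningful and all distances carry a
± 1 voxel uncertainty. This convention also makes the anatomical
invariant "tether length ≥ vesicle distance" hold by geometry to within
one voxel diagonal, which the suite asserts on noisy phantoms.

**Bridge length** $L$: the minimal geodesic path length through the
segment's voxel set between its two contact sets (voxels 26-adjacent to
each boundary), with Euclidean step weights 1, √2, √3 voxels. Curvature
therefore contributes to $L$; a straight rod spanning a $g$-voxel gap
measures $g-1$ voxels (contact centre to contact centre), and a segment
whose two contact sets share a voxel measures 0.

A consequence worth knowing: for a strongly curved *thick* tube the
minimal geodesic hugs the tube's inner edge, so it undershoots the
centreline arc length by roughly the rod radius times the total turning
angle (≈ π·r for a semicircle). This is a property of the definition, not
a bug; the phantom's curved bridges are therefore shallow circular arcs
(sagitta 0.25 × chord, 1-voxel rod) for which the measured geodesic
tracks the planted centreline arc within one voxel diagonal while staying
strictly above the chord. Tighter bends are generated faithfully but
their measured length should be interpreted as the inner-path length.

**Classifications** (all intervals left-closed, right-open, one
convention everywhere): tether lengths < 6 nm (short), 6–12 nm
(intermediate), 12–24 nm (long), ≥ 24 nm retained as "extra"; SV states
< 5 nm (SNAP25-dependent), 5–10 nm (intermediate), ≥ 10 nm
(Munc13-independent). Counts: each tether increments one vesicle, each
connector two; a vesicle is *tethered* at ≥ 1 and *multiply tethered* at
≥ 3 tethers.

**Layers and zones.** The presynaptic cytoplasm (vesicles included) is
cut into 1-voxel-thick shells by the exact Euclidean distance to the AZ
membrane; per shell, the fraction occupied by SV voxels is reported.
Zone aggregates use 0–45 nm (proximal), 45–75 nm (intermediate) and
75–250 nm (distal); all analyses stop at 250 nm. Voxel counts are
integers, so the conservation law — summed per-layer SV counts equal
total SV voxels in range — holds exactly and is asserted on every
phantom.

**AZ membrane area** (for the surface concentration of proximal SVs, per
µm²): counting exposed voxel faces overestimates oblique surfaces by up
to √3, and the blanket stereological 2/3 correction breaks on
axis-aligned patches. The default estimator therefore weights each
exposed face by $1/(|n_x|+|n_y|+|n_z|)$, with the local unit normal taken
from the gradient of a Gaussian-smoothed mask, and halves the total
because a thin sheet exposes two faces per unit of midline area. It is
exact for axis-aligned sheets and within ~10% for spherical caps; plain
face counting with the 2/3 factor remains available as a fallback.

**Model span screen.** `model_span()` reads an atomic model (PDB/mmCIF
via bio3d) and returns the minimal inter-atomic distance between two
residue-range selections, in nm — the membrane-to-membrane span a rigid
tether-forming molecule needs. `tether_accommodates()` then asks whether
a geodesic path at least that long exists inside a segment (the longest
shortest-path over contact pairs). This is a geometric feasibility
screen, deliberately weaker than rigid-body density fitting. Because no
deposited structure ships with the package, `synthetic_munc13_model()`
builds a clearly-labelled synthetic stand-in — a ~16 nm curved rod of CA
pseudo-atoms flanked by a compact C2B-like cluster, mirroring the
published domain architecture of the Munc13 core fragment — whose
C2B-to-rod-C-terminus span measures ≈ 13.8 nm. Conclusions about the
real molecule require the real coordinates; the function accepts any
local PDB/mmCIF file and residue selections.

## The phantom generator

`phantom_spec()`/`generate_phantom()` emulate exactly the features the
pipeline measures: a membrane slab with a central AZ patch (plasma
membrane outside it, postsynaptic side labelled excluded), spherical
vesicles whose centre heights are derived from prescribed edge-to-edge AZ
distances, and bridges rasterized as tubes swept along waypoint polylines
— straight, shallow-arc, or exactly semicircular. Bridges exist only in
the grayscale density, as in real data; the label volume carries
boundaries only. The ground truth stores the planted distances and the
polyline arc lengths, so recovery tests compare measured against
constructed values, never against the pipeline itself.

Realism choices, and their limits:

* **Contrast** is structure-low, binary before noise. Real tomograms
  have textured membranes, crowding, and other macromolecules; a phantom
  pass demonstrates correctness of the geometry and selection logic, not
  detection performance in crowded cytoplasm.
* **Noise** is additive Gaussian with σ defaulting to 0.5 of the
  membrane–background contrast (SNR 2), a level typical of 4×-binned
  Volta-phase-plate reconstructions. No CTF or reconstruction artefacts
  are modelled: the pipeline consumes reconstructed volumes, so noise
  realism beyond an SNR scale is out of scope.
* **Missing wedge**: `apply_missing_wedge()` zeroes the Fourier wedge
  left unsampled by a ± `halfangle_deg` tilt series about the x or y
  axis, producing the characteristic elongation along the beam axis.
  It is a geometric filter, not a tilt-series simulation.
* **Geometry**: the AZ is planar; synaptosome AZs are gently curved, and
  the area estimator is validated on spherical caps for that reason, but
  phantom unit tests use the planar patch.

The reference recovery target (`example_phantom_spec()`) is a 128³
volume at 1.4 nm/voxel — the paper-scale pixel size — with six 20 nm
vesicles at AZ distances 3–18 nm, eight tethers (two slanted, one shallow
arc) and four connectors. The noisy variant (`noisy_phantom_spec()`) is
64³ with two vesicles and noise at the default SNR.

## Statistics

The statistical layer mirrors standard practice for this experiment
type: values of per-structure variables are pooled across the synapses
of a condition, fractions are computed per synapse and summarized as the
mean with the SEM between synapse means (undefined, and reported `NA`,
for a single synapse). Testing is restricted to a configured list of
planned, orthogonal pairs — `comparison_design()` holds exactly the
pairs you give it, and no multiple-testing correction is applied because
the design object enforces that restriction instead.

Test choices per variable kind: Student's t for continuous approximately
normal values (Welch available by flag; Student is the default because
equal-variance t is the field's stated convention and group variances of
pooled structure variables are comparable), Kruskal–Wallis for counts
and other non-normal values (kept even for two groups rather than
switching to a different rank test), Pearson χ² without continuity
correction for frequencies (the per-condition structure counts are in
the hundreds, where Yates' correction is immaterial; results with an
expected cell < 5 carry a flag, < 1 additionally warns), and Pearson
correlation for associations. All tests are two-tailed; stars follow
*P* < 0.05, 0.01, 0.001. Degenerate inputs return *p* = 1 with a warning
rather than `NaN`.

**CDF inflection points.** The empirical CDF is smoothed with a
moving-average of fixed bandwidth (default 1 nm, exposed in config); the
regions where its derivative exceeds half its maximum are the "steep
increase" regions, and each region's midpoint is an inflection point.
When those regions cover most of the data range (default ≥ 75%) the
derivative is flat and no inflection is reported, rather than an
arbitrary midpoint. Multimodal samples yield one region per mode.

**Orientation equalization.** Synapse orientation (membrane-normal angle
to the x axis) modulates how the missing wedge attenuates bridges, so
before any tether/connector analysis the study removes synapses — always
the most extreme angle relative to the grand mean, from the group whose
mean deviates most (ties resolved toward the group holding the globally
most extreme synapse) — until all pairwise group-mean differences are
within tolerance (default 5°, exposed; the removal log is part of the
manifest). Removed synapses stay in distance and layer analyses, which
the wedge affects far less. A group is never emptied; an unreachable
tolerance raises an error instead.

## Problem sizes and determinism

The suite runs the oracle-equivalence comparison on fifty 10³ random
grids with four thresholds, full recovery on the 128³ reference phantom,
the length-versus-distance invariant on twenty noisy 64³ phantoms, the
χ² size check on 500 replicates of 300 + 300 simulated vesicles, and the
two-state discrimination at 300 vesicles per condition — sizes chosen so
each property is exercised at meaningful scale while the whole suite
stays interactive. Every random draw is seeded; identical specs produce
bit-identical volumes, tables and result files, and the JSON manifest
(config, seeds, removals, schema version) suffices to reproduce a run.

## Known limitations

* Multi-boundary components are rejected, not split; a bridge genuinely
  touching two SVs and the membrane is dropped.
* Contact creep: a bridge hugging a boundary for several voxels extends
  its contact set and can shorten the measured geodesic; real curved
  tethers attached tangentially are affected the same way.
* The vesicle radius from label spheres is a sphere-equivalent radius to
  the traced membrane midline; inner/outer leaflet conventions are not
  distinguished.
* The accommodation screen ignores density values inside the segment and
  never replaces rigid-body fitting.
* Phantom realism bounds what green tests prove: performance on real,
  crowded, CTF-affected tomograms must be validated on real data.
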