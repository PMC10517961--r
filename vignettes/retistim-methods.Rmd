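---
title: "Models and methods behind retistim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retistim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retistim)
```

`retistim` is a forward model of transcorneal electrical stimulation
(TES) of the rat retina: a voxel volume conductor, two compartmental
retinal neurons, and a threshold/safety analysis layer. This vignette
documents the models, their assumptions, the tunable parameters, the
numerical choices, and what the package's defaults do and do not
represent.

## The volume conductor

### Geometry

`build_head_eye_model()` voxelizes a parametric head-eye geometry on a
uniform lattice. Defaults (all config-overridable through
`head_eye_config()`):

| parameter | default | unit | note |
|---|---|---|---|
| voxel edge | 0.2 | mm | one computational cell per voxel; 1e6 cells |
| domain | 20 × 20 × 20 | mm | head block |
| eye diameter | 6.3 | mm | adult rat globe |
| retina shell | 0.2 | mm | posterior shell, homogeneous 1.5 Ω·m |
| cornea cap | 0.3 mm thick, 45° half-angle | | anterior, faces +z |
| lens diameter | 3.5 | mm | anterior chamber |

The head block is muscle with a one-voxel skin shell and a fat layer
beneath it, a cancellous-bone slab and a brain compartment behind the
eye. Tissue resistivities are the measured rodent values
(`default_tissue_table()`); the retina is deliberately homogeneous at
1.5 Ω·m, the averaged value for a degenerated retina. The eye dimensions
are standard adult-rat anatomy; they are not fitted to anything, and the
analysis layer reports threshold *ratios*, which are insensitive to
moderate geometric error.

Because a one-voxel curved shell labelled by voxel-centre distance can
leave pinholes, a sealing pass relabels any vitreous voxel with a
face-neighbour outside the eye as retina (or cornea inside the cap), and
the builder verifies along sampled radial rays that the shell is at
least one voxel thick everywhere.

### The admittance network

Each voxel is an electrical node; 6-neighbours are connected through the
shared face by two half-voxel resistors in series,

$$G_{ij} = \frac{2h}{\rho_i + \rho_j},$$

with open circuits across exterior faces (a body-in-air, insulating
boundary — the paper-scale model's boundary treatment is not published,
and insulating boundaries are the standard choice). Electrodes are not
meshed as conductors: `place_electrode()` maps a ring's centreline (or a
needle's exposed shaft) to the nearest lattice nodes, and
`solve_unit_field()` splits ±1 A equally across the stimulating and
return node sets. Equipotential metal is therefore not enforced; at the
reduced resolution used here the difference is small compared to the
geometric simplifications, but it is a known limitation.

The nodal system is singular up to an additive constant; one node (the
return node nearest the return set's centroid) is grounded. Large
systems are solved by conjugate gradients with a shifted incomplete
Cholesky IC(0) preconditioner (compiled; Jacobi fallback on
factorization breakdown) to a relative residual of 1e-8; systems below a
few thousand nodes may use a dense direct solve, which is the oracle
path for the reciprocity tests. Potentials are read off anywhere in the
domain by trilinear interpolation (`potential_at()`), which is exact at
nodes and for fields linear in position.

**Gauge convention.** The discrete solution is referenced at the
grounded node; the analytic point-source oracle
$V = \rho I / (4\pi r)$ is referenced at infinity. The oracle tests
therefore fix the one-constant gauge by matching the mean potential on
the outermost probe shell only, then check the $1/r$ profile at all
interior radii — one constant, fixed at one radius, tested over a range.

**Quasi-static scaling.** All tissues are purely resistive, so the field
for any stimulus current is the unit-current solution scaled by the
waveform. One linear solve per electrode configuration serves every
amplitude and pulse shape.

### Electrode presets

* **TES1** — stimulating ring on the temporal side of the eyeball,
  return ring mirrored on the nasal side, both lying on the eye surface
  (3 mm centreline diameter).
* **TES2** — stimulating ring on the cornea; return needle in the
  temporal head tissue. The needle tip sits 2 mm temporal of the eye
  surface, level with the posterior pole, with a 5 mm shaft running away
  from the cornea. This is the anatomically natural subdermal placement
  and routes the return current through the posterior eye, which is what
  gives TES2 its depth-wise (retina-crossing) field.

## The cells

### Morphologies

`build_db4_bc()` builds the spiking DB4 bipolar cell as a five-region
chain along the retina-depth axis — terminal, presynaptic terminal, axon
(35 µm × 1 µm), soma (10 µm, cylinder of equal diameter and length) and
dendrite — 65 µm tall in total. The section dimensions are not published
for this cell; the defaults are typical of DB4 cells spanning the inner
retina and are config-overridable. `build_a2_rgc()` builds the A2
ganglion cell: 20 µm soma, a stylized planar bifurcating dendritic arbor
spanning exactly 320 µm tip-to-tip, and a 1000 µm axon split into axon
hillock (40 µm, tapering 2→1 µm), sodium-channel band (40 µm), narrow
segment (90 µm × 0.4 µm) and distal axon (830 µm). The arbor is stylized
rather than a reconstructed tracing; `read_swc()` accepts a standard SWC
reconstruction as a drop-in replacement.

`compartmentalize()` splits sections into compartments of at most 5 µm
(BC) or 10 µm (RGC), with frustum lateral areas and midpoint-to-midpoint
axial resistances from the intracellular resistivity (100 Ω·cm BC,
110 Ω·cm RGC; Cm = 1 µF/cm² both). Channel densities attach by region
from `bc_channel_table()` / `rgc_channel_table()`, which reproduce the
published density tables exactly (the A-type K density is slaved to
3·g_K, the Ca-activated K density to 0.004·g_K; leak is uniform,
0.033 mS/cm² for the BC and 0.05 mS/cm² at −60 mV for the RGC).

### Kinetics: declared substitutes, calibrated once

The source literature for these cells does not print rate equations, so
the shipped registries are substitutes assembled from the standard
retinal modelling literature: the Fohlmeister–Miller-lineage α/β rates
for the ganglion-cell five-conductance set (Na m³h, K n⁴, A-type a³h,
Ca c³ with a single calcium pool driving K_Ca), standard HCN and T-type
forms, and HH-style inf/τ kinetics for the bipolar set. Every constant
lives in the registry object and in YAML mirrors
(`inst/extdata/kinetics_*.yaml`, schema in `?read_kinetics`), so an
exact replication of any published set drops in without code changes.

Two properties were used as calibration targets, once, before any
threshold analysis was frozen:

* a stable resting state (no spontaneous activity; `settle_cell()`
  criterion max |dVm/dt| < 1e-5 mV/ms), which constrains the resting
  activation/inactivation balance of the large axonal Na conductances;
* the qualitative strength-duration ordering of the two cells — the
  bipolar cell is the harder target at short pulses and the BC/RGC
  differential threshold shrinks as pulses lengthen. This fixed the
  bipolar Na activation as fourth-order with a slow time constant
  (τ_m = 1 + 4·exp(−((V+30)/20)²) ms), in line with the slow, small
  sodium "spikelets" bipolar cells actually fire. A conventional fast
  m³ activation makes the compact cell's strength-duration curve
  unrealistically flat below a millisecond.

Absolute threshold amplitudes were not calibration targets; the
placement-selectivity ratios are invariant to uniform excitability
scaling because the extracellular drive is linear in the stimulus.

### Cable integration

`simulate_cell()` solves

$$C_i \frac{dV_i}{dt} = -I_{\text{ion},i}(V_i)\,A_i +
\sum_{j \in \mathcal{N}(i)} \frac{(V_j + V_{e,j}) - (V_i + V_{e,i})}{R_{ij}},$$

with $V_{e,i}(t)$ the unit-current potential at compartment $i$ scaled
by the waveform — the one-way field-to-cell coupling (no ephaptic
feedback; fields are computed without the cell present). Each step
advances the gates by the exponential-Euler closed form at the current
voltage, then solves the membrane equation implicitly with the ionic
conductances frozen at the new gate values; the tree-structured linear
system is eliminated in O(n) by Hines ordering (parents before
children). Both kernels are compiled (`src/cable.cpp`); a pure-R
reference of the gating, current and calcium updates lives in
`R/kinetics.R` and is cross-checked against the compiled path in the
tests. Defaults: dt = 0.01 ms, initial state Vm = −65 mV with gates at
steady state, settle until max |dVm/dt| < 1e-5 mV/ms (cap 2000 ms,
cached on the cell), calcium pool with a 0.1 µm-shell influx factor and
10 ms extrusion.

Only potential *differences* along the cable drive it: a spatially
uniform Ve, however large, leaves Vm untouched (tested), and flipping
both the waveform polarity and the field sign reproduces the identical
trajectory.

### Spike detection and the stimulus artifact

Spikes are upward crossings of 0 mV at the detection compartment (axon
midpoint for the BC, distal-axon midpoint for the RGC — the published
work states only that "action potentials" define threshold), with
linearly interpolated crossing times and a 1 ms refractory rule, counted
from stimulus onset to 10 ms after stimulus end. At the large amplitudes
the reduced model requires, the passive (linear) deflection at the
detection compartment can itself approach the detection level during
short pulses. `find_threshold()` therefore subtracts the linear
response — a passive twin of the cell simulated under identical drive —
and detects on the active departure. The passive response is exactly the
linear part of the dynamics, so this is artifact removal, not a changed
criterion, and it preserves the linear-scaling properties (both
components scale with amplitude).

## Threshold analysis

`find_threshold()` brackets by doubling from a seed until a spike occurs
(default cap 1e6 µA; the end-to-end experiment configs raise their own
search cap to 1e9 µA because the least excitable configuration — the
bipolar cell under TES1 at sub-millisecond pulses — genuinely exceeds
1 A in this reduced model), then narrows by geometric bisection to a 2%
relative bracket and returns the upper (suprathreshold) end. Geometric
bisection makes the result exactly inversely proportional to any uniform
field scaling. `strength_duration()` runs the default
{0.1, 0.3, 1, 3, 10, 25} ms grid (the published range endpoints are 0.1
and 25 ms; the interior grid is this package's choice), warm-starting
each bracket at the previous duration's threshold. Monophasic thresholds
default to the minimum over the two polarities, because which polarity
excites a cell under a distant surface electrode is a geometric fact of
the induced field (at this site the bipolar cell is an anodic-phase
target). `threshold_ratio()` divides matched curves pointwise.

**Cell placement.** Both cells sit at the central-retina site opposite
the cornea, offset 0.5 mm temporally — a point inside the central-retina
analysis region; the exact on-axis point is a degenerate symmetry point
of TES1 at which the bipolar drive vanishes identically, which no real
(asymmetric) anatomy realizes. The bipolar cell runs radially with its
dendritic apex 15 µm from the scleral boundary: in the degenerated
retina being modelled, the photoreceptor layer is lost and the inner
nuclear layer abuts the outer boundary. The ganglion cell lies
tangentially with its soma near the vitread surface and its axon running
nasally, toward the optic disc.

## Shannon safety

`shannon_point()` computes charge per phase Q = I·t (µC), charge density
D = Q/area (µC/cm²) and k = log10 Q + log10 D; `max_safe_amplitude()`
returns the largest tested amplitude with k ≤ 1.5 (the no-damage
boundary; k = 2 marks observed damage). The electrode area is the full
geometric torus surface 4π²Rr with R = (inner diameter + wire
diameter)/2, which reproduces the 100 µA verdict for 10 ms phases;
`contact_fraction` is exposed because corneal contact plausibly covers
only part of the wire, and halving the area raises every k by exactly
log10 2.

## What the defaults do and do not represent

The default model is a deliberate reduction: a uniform 0.2 mm lattice
(1e6 cells) instead of a ~4e8-cell multi-resolution anatomical model, a
slab-and-shell head instead of segmented anatomy, two isolated cells
instead of a retinal network, substitute kinetics instead of the
unpublished originals, and equal current split instead of equipotential
metal. Quantities that survive this reduction — and are what the tests
assert — are ratios, orderings and curve shapes: the tenfold TES1/TES2
selectivity for bipolar cells, the sub-unity ganglion-cell ratio, the
non-increasing monophasic strength-duration curves, the shrinking BC/RGC
differential with pulse duration, and the closed-form Shannon verdict.
Absolute threshold amplitudes are *not* comparable to in vivo
measurements (tens of µA at the superior colliculus): the modelled cells
sit in the central retina far from the electrode, the lattice is coarse,
and the in vivo measurement integrates the whole retina including the
periphery near the ring. The in vivo outcomes of the source study
(collicular thresholds, fundus and histology percentages) are
experimental results outside the scope of any forward model.

## Problem sizes and runtimes

The test suite rebuilds everything from code: the full reduced model
(1e6 cells, two field solves at ~300 CG iterations each), both cells
(13 and 198 compartments), 36 threshold searches across the duration
grid, and the small-grid oracles (dense reciprocity at 729 nodes,
point-source at 41³). The complete suite runs in a few minutes on one
CPU; the bundled `fig2b.yaml` end-to-end experiment takes about three.
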