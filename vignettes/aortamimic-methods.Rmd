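---
title: "Designing and analysing lattice-reinforced aortic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing lattice-reinforced aortic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortamimic)
```

## The problem

The aortic wall is a strain-stiffening soft tissue: compliant at
physiological strains, with an incremental elastic modulus
$E_{inc}(\varepsilon) = d\sigma/d\varepsilon$ that rises steeply as
collagen fibres are recruited. Printable photopolymers strain-soften
instead. Multi-material printers can approximate tissue behaviour with a
*lattice reinforcement* (LR): a rigid tessellated microstructure embedded in
a flexible matrix, so that the composite's stiffness is governed by the
lattice geometry. This package implements the two halves of that workflow —
procedural lattice design and the uniaxial tensile-test analysis used to
characterise the printed samples — plus a synthetic-data generator that
stands in for instrument exports, which for the motivating experiments are
available only on request.

## Lattice design

### Unit cells

Four parametric cells are generated (`unit_cell_spec()`,
`build_unit_cell()`). Their published description fixes the native
envelopes — chain and knitted cells derive from a regular hexagonal prism of
5 mm radius and 5 mm height split at mid-height, the origami from a 5 mm
cube, the diamond crystal from a unit cube — but leaves the internal
geometry open. The constructions used here, and why:

* **Chain.** Two flat hexagonal links (extruded hexagonal annuli with a
  square strut cross-section equal to the configured thickness), stacked
  with a z-clearance and shifted so the upper link reaches into the lower
  link's opening: a flattened chain, the only arrangement of interlocked
  rigid links that fits a cell shorter than 2 mm inside a 2.6 mm slab. The
  in-projection clearance between links is $d = L/3$ with $L$ the link
  length (`link_gap_ratio`, default 1/3). A hexagonal annulus extruded by
  $t$ between centreline circumradius $R$ gives volume $6Rt^2$ exactly,
  which makes the volume accounting closed-form.
* **Knitted.** A single jersey (stockinette) loop lying in the slab plane,
  swept with a circular yarn cross-section and undulating out of plane.
  Published sources do not give the loop proportions; the loop's
  width/height follow the native prism aspect (width = prism radius,
  height = flat-to-flat span), which is the calibration that reproduces the
  reported lattice occupancy (see below). This is stated openly: the loop
  geometry is otherwise unidentifiable from the text.
* **Diamond crystal.** The diamond-cubic beam lattice — 16 tetrahedral
  bonds between the 18 sites of the conventional cell — with cylindrical
  struts. The commercial library cell it emulates is unpublished; diamond
  cubic is the canonical "diamond crystal" beam lattice.
* **Origami.** A Miura-ori sheet represented as a height field over the
  square cell, folded in a herringbone arrangement (the in-plane shear of
  classic Miura folded back on itself) so the cell stays square in plan and
  tiles without overhang. The sheet is thickened by a *vertical* offset of
  ±t/2, which makes the solid's volume exactly plan-area × thickness
  regardless of the folds and keeps the solid trivially watertight.
  `fold_angle` (default 60°) sets the in-plane zigzag of the fold lines;
  the fold amplitude is fixed by the cell-height convention below.

### Resizing and tessellation

`tessellation_config()` mirrors the three design-table controls: "size in
z" (with aspect ratio kept), inter-cell "spacing", and "thickness". Two
conventions had to be decided because the originating CAD tool does not
document them:

* **Thickness is applied after resizing.** The cell skeleton is rebuilt at
  the target size and struts are thickened to the configured value in final
  millimetres. Scaling an already-thickened 5 mm cell down to 1.5 mm would
  shrink a 0.6 mm strut to 0.18 mm and make the chain lattice occupy about
  1 % of the slab instead of the reported ~13 %, so the rebuilt-skeleton
  reading is the only one consistent with the published volume fractions.
* **"Size in z" is the thickened cell's z-extent.** With the origami's
  0.75 mm sheet inside a 1.5 mm cell, measuring the skeleton instead would
  push the design's volume fraction to ~36 % against the reported 25.33 %.

Cells are placed on a regular grid with pitch = cell extent + spacing, and
only whole cells are kept (printed lattices show complete links and loops
at the slab edges). The per-axis count is

$$n = \left\lfloor \frac{\text{slab} + \text{spacing}}{\text{cell} + \text{spacing}} \right\rfloor,$$

i.e. the trailing inter-cell gap does not need to fit. The alternative
(floor(slab/pitch)) would leave the knitted design with zero cells in z
(2.0 mm cell + 1 mm spacing in a 2.6 mm slab), contradicting the fact that
the knitted lattice was printed; the adopted rule reproduces the published
origami grid of 42 × 6 × 1 cells exactly. The diamond cell additionally
declares a nominal tiling extent equal to its cube side, so its grid pitch
is exactly the cell size and corner struts of neighbouring cells meet.

### Volumes, Booleans, and the voxel oracle

Meshes are closed triangle soups with per-face part labels. Volumes come
from the divergence theorem, which is exact for closed non-self-intersecting
parts; chain, knitted and origami cells are built overlap-free so their
volumes are exact. Diamond struts meeting at a node overlap slightly, so
union volumes (used by `volume_fraction()`) are measured with a column-ray
voxelization (`mesh_volume_voxel()`): vertical rays on a jittered 2D grid,
exact in z, midpoint quadrature in x/y, intervals unioned across parts.
The same routine serves as the independent oracle that the divergence
volumes are checked against at 0.05 mm pitch (1 % agreement in the tests).

Boolean embedding (`embed_lattice()`) exploits that every cell lies
strictly inside the slab: the difference "slab minus lattice" is exactly
the slab boundary plus the reversed lattice boundary, so matrix + lattice
volumes are additive to the slab volume by construction and the result
stays watertight. Vertices are never merged across parts; watertightness
is every directed edge appearing exactly once with its reverse present.

With these conventions the four design-table lattices land at
(tests recompute these): chain ≈ 11.8 % (reported 12.81 %), knitted ≈ 2.7 %
(3.19 %), diamond ≈ 6.7 % (7.58 %), origami ≈ 25.2 % (25.33 %) — all within
the ±2 percentage-point band that the under-specified strut cross-sections
and the unknown commercial diamond cell warrant.

### Vessel walls

`offset_wall()` thickens a closed inner (blood-pool) surface along
area-weighted vertex normals — the parametric stand-in for the 2 mm wall
offset used on segmented aortas — and errors when the offset exceeds the
local radius of curvature (detected as flipped outer faces).
`conformal_tessellate()` maps the diamond skeleton through a UV
parameterization of the mid-wall (u = circumference / 2.75 mm,
v = centreline arc length / 2.75 mm), with the radial coordinate scaled so
strut surfaces stay strictly between the wall surfaces (default 0.5 mm
strut thickness centred at mid-wall, `height_offset = 0.5`). Whole-cell
rows/columns only, so the cell count matches the analytic area estimate to
within one row plus one column.

## Tensile analysis

The processing order follows the published flow literally: per-sample
engineering stress/strain → interpolation onto a common grid → downsample
by 10 → zero-phase 2nd-order Butterworth low-pass at 0.1 Hz → average
across samples → central differences → the same filter again → E_inc
restricted to 15–90 % of test duration. Numerical choices:

* **Conditioning removal.** Records start with a preload and three 0–1 N
  loading–unloading cycles; `compute_stress_strain()` trims to the final
  monotone ramp by starting at the last sample at (or below) zero
  displacement. Summaries always use post-trim raw data.
* **Common grid.** Interpolation is linear onto a fractional-duration grid
  whose length is the median raw length (the sources do not state one);
  endpoints are preserved, and curves under 10 samples are rejected.
* **Cutoff interpretation.** 0.1 Hz is taken at the post-downsampling rate
  (10 Hz nominal). At the raw 100 Hz rate the cutoff would sit at 0.1 % of
  Nyquist and flatten the curve shape entirely.
* **Zero phase.** Filtering is forward–backward so the averaged curves are
  not phase-lagged. The implementation pads by odd reflection and starts
  each pass from the steady state of the endpoint value (the standard
  filtfilt initialization), otherwise edge transients of a growing
  stress signal leak ~10 % errors into the window; with it, the pipeline
  returns a noiseless linear material's modulus exactly and tracks the
  tissue model's analytic $ABe^{B\varepsilon}$ within ~1 % inside the
  window (asserted at 2 % and 5 % in the tests).
* **Derivatives.** $E_{inc} = (d\sigma/dt)/(d\varepsilon/dt)$ with central
  differences on both channels; points with vanishing strain rate (below
  10⁻³ of the peak rate) are masked with a warning.
* **Summaries.** Max stress and its strain come from raw, unfiltered
  curves, first index on ties; dispersion is the sample standard deviation
  with CoV = σ/μ; n = 1 batches get flagged dispersion. They are invariant
  to the filter configuration by construction (tested).
* **Order of filtering vs averaging.** The text is ambiguous; the default
  filters each sample then averages, and `average_first = TRUE` exposes the
  other reading.

Comparisons use Welch's unequal-variance t from summary moments (the
sources name only a "one-tailed t-test"; Welch is the safe default when
per-sample data are unavailable), one-sided at 5 %. A pair is classified
"greater"/"smaller" when the corresponding one-sided test rejects and
"equal" when neither does — the two-one-sided convention is this package's,
since the original direction choices are unpublished. Literature reference
rows carry no sample sizes, so comparisons assume `assumed_n` (default 6,
matching the printed batches); this choice changes equality calls and is
therefore a prominent, per-call parameter.

## Synthetic data

Three closed-form material laws emulate the specimens the analysis is
designed for: polymers $\sigma = a\varepsilon/(1+b\varepsilon)$ (tangent
modulus strictly decreasing — chosen precisely to reproduce the
strain-softening controls), tissue-like materials
$\sigma = A(e^{B\varepsilon}-1)$ (a 1-D proxy for the exponential
anisotropic response of the arterial wall; the full anisotropic model is
out of scope), and a composite $(1-f)\,\sigma_m + f\,\sigma_l$ whose total
stress drops by a configured fraction at the matrix-rupture strain and
continues (lattice-only stretch) to final rupture — mirroring the observed
behaviour of a stiff chain lattice inside a soft matrix, where the matrix
fails around 70–80 % strain while the lattice stays connected and the
measured incremental modulus goes negative.

Records are constant-rate ramps (10 mm/min) sampled at 100 Hz on a 10 mm
gauge with the printed-slab cross-section (10.13 × 2.60 mm), preceded by
three triangular conditioning cycles sized to reach 1 N. Noise is additive
Gaussian on the load channel (default 0.01 N — no instrument noise figure
is published, so this is an explicit placeholder) plus a multiplicative
per-specimen stress-scale jitter with coefficient of variation 0.05
(default), drawn once per specimen. Sub-seeds are `seed * 1000 + i`, so
batches are reproducible and records independent. Only the stress scale is
jittered by default: jittering the rupture strain of a stiffening material
would inflate the max-stress CoV several-fold above the configured value
and break the interpretation of `inter_sample_cov`.

What the generator deliberately does **not** emulate: viscoelasticity and
rate dependence, anisotropy, grip slippage and compliance, true-stress
effects at large strain, temperature, and print-orientation effects.
Passing tests therefore demonstrate that the *pipeline* recovers what the
generator put in — not that real printed specimens behave like the models.

## Problem sizes and runtime choices

The test-suite and acceptance studies use batches of n = 6 specimens
(matching the printed batches), 60 s records at 100 Hz, 200 replicates for
the parameter-recovery study, voxel pitches of 0.05 mm for the oracle
checks and 0.02 mm for diamond union volumes, and single unit cells (not
whole lattices) for voxel comparisons, since cells of a tessellation are
disjoint translates and union volume scales with the count. The recovery
study generates uncycled records (conditioning trimming is the identity
there and is tested separately).

## Limitations

* The chain, knitted and diamond geometries reproduce the reported volume
  fractions only within a couple of percentage points; the exact printed
  strut cross-sections and the commercial diamond cell are unknown.
* The conformal tessellation targets parametric tubes (centreline + radius
  profile); patient-specific segmentation import is out of scope.
* Boolean embedding relies on the lattice lying strictly inside the slab;
  lattices touching the slab boundary would need a general mesh Boolean.
* The relation classifier inherits the `assumed_n` convention; published
  qualitative statements are reproduced at `assumed_n = 6`, but equality
  calls can change for other assumed sizes.
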