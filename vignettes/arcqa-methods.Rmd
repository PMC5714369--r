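---
title: "arcqa: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{arcqa: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcqa)
```

# Scope and model

`arcqa` is a desk-scale re-implementation of cylindrical diode-array QA for
VMAT: everything a verification workflow touches — detector geometry, plan
and dose objects, fluence reconstruction, a dose engine, gamma analysis,
and the sensitivity studies — runs on synthetic fixtures. The dose engine
is deliberately a *primary-ray stand-in* for a Monte Carlo code or a
treatment planning system, not a dosimetry engine: it exists so that every
downstream comparison (gamma, misalignment, angular response) has a
consistent, deterministic ground truth.

## Coordinate conventions

Fixed frame with the phantom supine: `x` right–left (+x patient left),
`y` anterior–posterior (+y anterior), `z` superior–inferior along the
cylinder axis. Gantry 0° places the source anterior at `(0, SAD, 0)`;
gantry 90° lateral at `(SAD, 0, 0)`. The spiral angle is measured from
anterior toward +x; the unwrapped cylinder map puts column 1 at the
angular origin (anterior by default). Couch rotation is a yaw about the
vertical (`y`) axis. These are documented constants: the physical device
does not prescribe them.

## Detector and phantom geometry

The spiral layout places `round(pi * diameter / spacing)` diodes per
revolution, advancing one pitch per revolution. Defaults (1 cm pitch, 1 cm
spacing, 21 cm diameter, 21 cm axial length) give 66 diodes/revolution for
21 revolutions = 1,386 diodes. The commensurability check is applied *per
inter-diode gap* (`|C/round(C/s) − s| ≤ 1e-3 cm`): the literal
circumference residual of the default device is 0.027 cm, so a
whole-circumference tolerance would reject the canonical configuration.
The stored `spacing` is the exact helical arc-length step.

Diodes are points: the 0.8×0.8 mm² active area is not modeled, because
readings are compared against point-interpolated dose at the same
granularity the vendor analysis uses.

Entrance/exit masks split the array by the sign of the diode position's
component along the isocenter→source direction; diodes exactly on the
dividing plane go to *entrance* (deterministic tie-break). Consequence: at
gantry angles where diodes sit exactly on the plane (e.g. 90° vs 270° with
the default layout), the masks swap except for those tie diodes, which are
entrance in both.

The phantom is two coaxial cylinders: acrylic shell (1.17 g/cc) between
26.59 cm and 15.0 cm diameters, core either plug (acrylic) or air
(0.0012 g/cc — the device's cavity density is not published; ICRU air is
used). Outside the phantom contributes 0 to effective depth, so buildup is
referenced to the phantom surface. Radiological paths are analytic
(line–circle intersections, midpoint-classified segments); a quadrature
oracle verifies them to 1e-3 cm in the tests.

## Beam model

TMR is analytic by default: linear buildup to `dmax`, then
`exp(−mu (d − dmax))`, normalized to 1 at `(dmax, 10×10)`. Defaults:
`6X` dmax 1.5 cm, mu 0.035 cm⁻¹; `10X` dmax 2.5 cm, mu 0.0275 cm⁻¹ —
textbook-scale values, configurable, because the measured beam tables are
not published. A tabulated TMR can be supplied. Field-size dependence is
accepted in the interface but ignored by the analytic default (no scatter
kernel: an equivalent-field argument without output factors would be
decoration). Calibration is 1 cGy/MU at dmax for 10×10 at 100 cm SSD.
Dose at a point is

```
meterset × calibration × fluence(ray) × TMR(d_eff) × (SAD / r)²
```

summed over projections. The in-field lateral profile is flat (no horns);
there is no penumbra, head scatter, or electron contamination. Doses are
carried in cGy (the calibration unit) end to end.

## Fluence model

Subfields are the segments between adjacent control points: meterset =
Δ(cumulative weight) × beam MU, aperture = midpoint of the bounding
apertures (the simplest unbiased interpolant; the delivery between control
points is not specified more finely), representative gantry = shortest-arc
circular midpoint (antipodal pairs resolve to +180° by convention). One
static projection represents each subfield; the `angular_bin` parameter of
`accumulate_fluence()` is the knob between per-subfield projections and
coarser composites.

Rendering: open = 1, under leaves inside jaws = transmission (default
1.5%), outside jaws = 0. Rounded leaf ends widen each gap by a dosimetric
offset (default 0.1 cm per tip); a tongue-and-groove strip (default
0.05 cm) on the open side of a boundary between leaves with different tips
is rendered at transmission, so a stagger of Δx removes exactly
`width × Δx` of open area. Leaf widths default to the 120-leaf pattern
(40 central pairs at 0.5 cm, 20 outer at 1.0 cm) and are configurable; the
transmission parameters are stand-ins, exposed in `mlc_model()`.

## Detector response model

Angular response is a symmetric raised-cosine lobe in the angle α between
the beam travel direction and the diode outward normal:
`factor = 1 − A sin²α`, A = 0.08 by default (the published magnitude of
the effect; its shape is not published). The factor is 1 at normal
incidence through either face and maximally depressed at grazing
incidence, which makes coplanar lateral deliveries nearly unaffected and
couch-rotated ones increasingly affected — the observed clinical pattern.
The vendor correction is modeled as division by the same factor
("perfect-model" correction): enabled correction with zero noise recovers
the unperturbed reading exactly, so correction-on study cells are exactly
100%. Noise is multiplicative Gaussian; every stochastic path requires an
explicit seed and restores the caller's RNG state.

## Gamma analysis

Global normalization to the reference maximum (the QA convention; a local
mode exists but is off by default — the analysis threshold, default 10% of
the reference maximum, is applied to the *reference* distribution). The
evaluated distribution is sampled on a lattice anchored to its own grid
with step ≤ DTA/10 chosen to divide the native spacing; the fast search
scans a window of radius 3×DTA and doubles it whenever
`min γ > radius/DTA` (a farther minimizer could still win), so it is
*provably identical* to the exhaustive search on the same lattice — the
suite asserts equality to 1e-6 against an independently coded brute-force
oracle. On the unwrapped cylinder the angular coordinate is periodic: arc
distances are measured along the surface, never through the 0°/360° seam.
The unwrap approximates each revolution as a row at its mean axial
coordinate; the sub-pitch helical offset within a row (< 1 cm) is folded
into the row, matching the vendor-style 2D unwrap.

The `shortcut` option accepts a point without spatial search when its
same-location dose difference is already within tolerance; the stored γ is
then an upper bound but pass/fail and passing rates are unchanged (the
suite asserts this). Studies use it; default calls do not. Reported rates
are formatted with one decimal in CSV exports.

# The synthetic world

`make_fixtures()` emits a DICOM-RT Plan, a DICOM-RT Dose computed from it
by the engine, and a diode readings table (with the central chamber dose
in its header). Defaults: one full arc, 177 equally spaced control points,
10×10 cm² jaws, 200 MU, 6X, 0.5 cm dose grid, ~2° projections, 1%
multiplicative reading noise — the control-point count and field size are
the canonical delivery configuration; MU is a typical two-fraction-scale
plan meterset; the noise is a realistic diode repeatability figure. All
randomness derives from the seed; identical spec + seed give byte-identical
files (instance UIDs are content-hashed, not timestamped).

Modulation patterns:

* `open` — static square field;
* `wedge` — a sliding-window sweep whose integrated fluence is flat within
  ±1.5 cm and wedge-shaped on the flanks. Both leaf edges travel: an early
  design with one static bank left a zero-penumbra step shared coherently
  by every arc projection, which is not a feature any physical delivery
  has (real edges carry ~5 mm penumbra);
* `multiseg` — three static segments carrying 50/30/20% of the meterset
  (stepped fluence);
* `arcsweep` — a 6 cm window whose center oscillates sinusoidally with
  gantry (5 cycles per arc). This is the misalignment-study fixture: its
  peripheral dose is strongly modulated azimuthally on a multi-centimeter
  scale while the window always covers the center, keeping the chamber
  volume's dose spread at the 0.01% level (the study design keeps it under
  1% so that point-dose comparisons are not gradient-limited).

Why `arcsweep` for misalignment: a penumbra-free engine turns any
gantry-correlated aperture edge, discretized into angular bins, into
sub-lattice fluence steps on the cylinder. Steps much sharper than the
1 cm diode spacing make the cylindrical array spuriously hypersensitive to
millimeter shifts — an artifact of the missing source model, not detector
physics. The oscillating window keeps all composite gradients at the
multi-centimeter scale the real modulated case has, and with it the
package reproduces the qualitative sensitivity pattern: rotations hit the
cylindrical array hardest (peripheral arc shift ≈ 1.8 mm/° at 10.5 cm
radius versus sub-millimeter interior shifts on a planar array), lateral
shifts hit the planar array hardest (full in-plane displacement versus the
cosine-projected apparent shift on a cylinder), and the central chamber
barely moves. Because single-cell orderings at 1–2 mm sit within lattice
aliasing, the acceptance tests compare *mean passing-rate drops* across
the tested magnitudes (RL 1/2/3/5/10 mm; rotations 1–3°) at 2%/2 mm and
3%/3 mm.

What a green test does **not** establish: agreement with any physical
device. The generator has no penumbra, scatter, output factors, leaf
timing, or per-diode sensitivity variation, and the "measurement" shares
the engine with the prediction — studies validate the *analysis chain*
(geometry, bookkeeping, gamma mathematics, directional physics), not
absolute dosimetry.

# Numerical choices

* DICOM: explicit VR little endian only, written with explicit lengths
  (undefined lengths are parsed for robustness). Dose voxels are stored as
  32-bit integers with `DoseGridScaling = max/ (2³¹−1)`; round trips are
  exact to one scaling step. Plan decimals use 10 significant digits
  (round trips to 1e-4 are asserted; metersets to 1e-9). Positions are
  DICOM-mm on disk, cm in memory.
* Chamber averaging: subdivision sampling on a ≤ 0.5 mm lattice symmetric
  about the probe center; partial voxels enter via their sample fraction.
  Verified against 10⁶-point Monte Carlo volume sampling to 0.1%.
* Grid interpolation at detector positions is trilinear — deliberately
  documented because reference-grid resolution is a first-order effect: on
  the bundled fixture the 3%/3 mm plan-QA rate rises from ~68% (1 cm grid,
  15° bins) to ~94% (0.5 cm grid, 2° bins), with the residual failures on
  the sharp field-edge rows. This mirrors the known grid-size pitfall of
  commercial dose calculations over the phantom's air cavity, and is left
  visible rather than smoothed away.
* Percent differences are reported as
  `100 × (measured − calculated) / calculated` (the calculation is the QA
  reference). A globally ×1.05 measurement therefore reads +5.0%.
* Ties and degenerate inputs: diodes on the entrance/exit plane →
  entrance; zero-meterset subfields are skipped; an all-zero reference
  distribution is "no evaluable points"; rotations are restricted to
  (−180°, 180]; antipodal circular midpoints resolve to +180°.

# Known limitations

* No source model: penumbra-free edges make edge diodes disagree with any
  smoothed reference; fixture design works around this, real data would
  not.
* The TMR stand-in has no field-size or spectral dependence; depth-dose
  claims are self-consistency claims.
* Axial-aligned dose grids only; oblique orientations are rejected.
* The DICOM codec covers the RT Plan/Dose subset used here; it is not a
  general DICOM implementation.
* The vendor's measurement-uncertainty inflation of passing rates is
  intentionally not modeled; reported rates are raw.
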