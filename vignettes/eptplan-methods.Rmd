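---
title: "Models and methods behind eptplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eptplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`eptplan` plans electroporation-based treatments (electrochemotherapy, ECT,
and irreversible electroporation, IRE) of deep-seated tumors. This vignette
documents the models, the tunable parameters and their defaults, what the
synthetic phantoms do and do not emulate, and the design choices made where
the problem was genuinely open.

## The physical model

Electroporation outcome is governed by the local electric field magnitude.
During a pulse the tissue behaves resistively, so the potential solves the
steady conduction equation

$$\nabla \cdot (\sigma \nabla u) = 0,$$

with the applied voltage as Dirichlet conditions on the active electrode
pair and insulating (homogeneous Neumann) outer boundaries. Electroporation
itself raises membrane conductivity, which we model as a field-dependent
conductivity: per tissue, $\sigma(E)$ is a cubic smoothstep from the
baseline $\sigma_0$ below $E_{low}$ to the post-electroporation
$\sigma_{max}$ above $E_{high}$ (exactly $(\sigma_0+\sigma_{max})/2$ at the
midpoint). Because poration is not undone within a pulse train, the update
rule is the voxelwise maximum $\sigma \leftarrow \max(\sigma, \sigma(E))$,
giving a nondecreasing, bounded — hence convergent — fixed-point iteration:
solve, compute $|E|$, raise $\sigma$, repeat until the largest relative
increase falls below `tol` (default 1e-3, cap 20 iterations; hitting the
cap sets a flag rather than erroring).

**Discretization.** Voxel finite volumes with a 7-point stencil and
harmonic-mean face conductivities (flux-continuous across material
interfaces), assembled sparse and solved by a direct supernodal Cholesky
factorization (`Matrix`/CHOLMOD; supernodal is ~16x faster than the default
simplicial mode on 3D 7-point patterns). The original clinical workflow
used tetrahedral FEM in a commercial package; the structured-grid solver
solves the identical PDE and is verified against the parallel-plate
(`U/d`, < 1%) and coaxial-cylinder (`U/(r ln(b/a))`, < 3% at 128^2
in-plane) analytic solutions, with discrete anode/cathode current balance
at 1e-6.

**Pulse sequence.** Voltages are applied to successive electrode pairs;
the cumulative field map is the voxelwise maximum of the per-pair fields.
The conductivity state is carried forward across pairs by default
(electroporation within a session is irreversible). A consequence worth
knowing: with carried conductivity the cumulative map genuinely depends on
the pulse order (we measured up to ~18% voxelwise on a mirror-symmetric
two-pair phantom, while the solver itself is mirror-consistent to 1e-10).
With `reset_sigma_per_pair = TRUE` each pair starts from baseline and the
cumulative map is exactly order-invariant. Both behaviors are tested.

**Units.** Spacing mm, conductivity S/m, fields V/cm, voltages V. The only
conversion (V/mm to V/cm) lives in `field_magnitude()`.

## Thresholds and protocols

Coverage is judged against protocol-dependent field thresholds: reversible
$E_{rev}$ (ECT goal: whole tumor above it) and irreversible $E_{irr}$
(ablation; also the collateral-damage metric for healthy tissue).
Thresholds are calibrated only for the two standard protocols — ECT
8 x 100 µs at 1 Hz and IRE 90 x 100 µs at 1 Hz; any other pulse setting is
a hard error asking for custom thresholds rather than a silent fallback.
Tissue values ($\sigma_0$, $\sigma_{max}$, transitions, thresholds) ship as
an editable JSON config of literature-derived nominal values
(`inst/extdata/tissue_properties.json`); none of them is a result of this
package, and the defaults (e.g. liver $\sigma_0$ = 0.11 S/m, ECT
$E_{rev}$ = 400 V/cm, $E_{irr}$ = 800 V/cm) exist to make the shipped
pipeline runnable, not to assert dosimetry.

## Voltage optimization

The planning objective is not uniquely determined by the clinical
workflow, so we chose: find minimal voltages (within `delta_u`, default
10 V; generator cap per electrode spec, default 3000 V for
variable-geometry needles) such that target coverage at $E_{rev}$ reaches
`required_coverage` (default 1.0, i.e. the entire tumor volume).
Healthy-tissue volume above $E_{irr}$ is reported, not constrained.
Coverage is monotone in every pair's voltage (the field scales with the
boundary value and the max-rule preserves order), so the search is a
bisection on a common voltage scale followed by a per-pair bisection
descent — deterministic, and verified against an exhaustive grid-search
oracle on a two-pair phantom. Infeasibility at the cap returns a flagged
plan instead of an exception, which the needle-count planner uses to add
needles (symmetric row, configurable spacing) until feasible or capped.

## Segmentation methods and their defaults

The method families are fixed; published parameter values are not, so all
numeric settings are arguments with defaults tuned on the phantoms:

- **Liver CT** (`segment_liver_ct`): Gaussian presmoothing (2 mm),
  soft-tissue band (-100..300 HU), Euclidean distance transform of the
  band mask, connected component containing the distance maximum (the
  deepest soft-tissue body; ties broken by the component search order,
  which favors larger bodies containing the unique maximum), then a
  morphological region-based (Chan–Vese-style) active contour: per sweep,
  reclassify a one-voxel band by the two-phase data term (inside mean vs
  local outside-ring mean) and smooth the indicator. The one-voxel step
  bound keeps the contour from jumping across background gaps into bone.
- **Liver MRI** (`segment_liver_mri`): region growing from the seed
  (tolerance default 25% of seed intensity), adaptive thresholding
  (clamped box mean, radius 6 voxels) as cleanup, same active contour;
  result is the component containing the seed. Growth touching > 50% of
  the volume border raises a leakage warning.
- **Vessels** (`segment_vessels`): multiscale Frangi vesselness (scales
  1–3 mm, alpha = beta = 0.5, c auto = half the maximal structureness)
  computed with non-liver voxels replaced by the median liver intensity so
  the organ boundary is silent; seeds = response above the 0.99 in-liver
  quantile and an absolute floor (0.1) **and** above the median liver
  intensity by `min_contrast` (30 HU). The contrast condition is load-
  bearing: the rim of a dark lesion is genuinely ring/tube-shaped and
  passes the geometric filter, but is not a contrast-filled vessel. Final
  mask = local threshold (box mean + k·sd, k = 0.25) in a 2-voxel
  neighborhood of the seeds, always within the liver.
- **Bone** (`segment_bone_ct`): threshold (300 HU), closing, minimum
  component size.
- **Canine brain** (`segment_canine_brain`): intensity band as fractions
  of the volume maximum (0.35–0.8, excluding the bright skull shell),
  per-slice erosion (2 voxels) and component labeling; the central slice
  maximizes the largest eroded component's area; propagation outward keeps
  components whose overlap fraction with the previous slice's mask is at
  least `min_overlap` (0.3) — "similarity of adjacent slices" is read as
  overlap-based, one of several defensible readings.

## Contour validation model

Masks are shown as per-slice closed contours (marching squares at the 0.5
iso-level via `grDevices::contourLines`, counterclockwise, holes dropped).
Point reduction uses the relevance measure
$K(p) = \beta \, l_1 l_2 / (l_1 + l_2)$ with turn angle $\beta$ in radians
— collinear points score 0 and vanish first — deleting the minimum
iteratively and recomputing only the two neighbors (sequential
re-evaluation is stabler than one-shot ranking); ties delete the lower
index. The default retention is 20% of the original points, `ceiling`-ed
at small counts (the rounding direction was unspecified; `ceiling`
guarantees the >= 3-point invariant cleanly). Edited (user-moved) points
are reconstructed with a chord-length-parameterized natural cubic through
the run of moved points anchored at their unmodified neighbors (periodic
if everything moved), sampled at 1-pixel steps with knots hit exactly;
moved points are then protected from deletion so the promised "your point
stays" contract survives re-reduction. Rasterization is scanline even-odd
fill with pixel-center inclusion; self-intersecting contours are rejected
naming the slice.

## Electrode model

The catalog (`inst/extdata/electrode_catalog.json`) covers the commercial
styles — hexagonal 7-needle, linear pair, finger axial/perpendicular, and
variable-geometry single needles. Exact manufacturer dimensions are not
public data we can verify, so the shipped numbers are explicitly nominal
and editable. The hexagonal pulse sequence is the conventional 12 pairs
(6 center–outer, 6 outer-ring); the ordering is cosmetic for the
cumulative map (tested). Arrays are strictly parallel by construction:
one direction vector, tips on the perpendicular plane through the target.

Rasterization labels voxels whose centers lie within the needle radius of
the active segment, with the capture radius floored at 0.75 of the largest
voxel edge — a deliberate deviation from pure center-inclusion, because a
1.2 mm needle on a 2.5 mm planning grid would otherwise rasterize to
nothing (the axis can pass ~0.71 voxel edges from every center). On grids
finer than the needle this floor is inactive and the labeled volume
converges to the analytic cylinder volume (tested with a 4 mm needle;
sub-voxel-radius circle counts oscillate by number theory, not error).

## Phantoms: what they emulate, what they do not

The abdomen phantom is an ellipsoidal liver (semi-axes 35/25/20 mm)
containing a straight 3 mm contrast vessel and a spherical tumor, on an
air-valued background, optional bone slab; CT intensities are
Hounsfield-like class means (air -1000, liver 60, vessel 150, tumor 30,
bone 700), MRI arbitrary units. Noise is additive white Gaussian — the
simplest model that stresses thresholding and region growing. The brain
stack's z semi-axis deliberately exceeds the stack so end slices retain
enough area for adjacent-slice overlap while the central slice stays the
unique maximum. Deterministic seeding: identical spec + seed gives
bit-identical volumes.

Not emulated: anatomical shape variability, imaging physics (beam
hardening, bias fields, partial-volume blur), textured parenchyma,
branching vasculature. A green segmentation test therefore establishes
that the implementation is faithful to its algorithm and robust to
additive noise at 10% contrast — not clinical-grade accuracy on patients.
Dice scores against phantom truth (liver >= 0.95 noiseless / 0.90 noisy,
vessels >= 0.7, bone >= 0.95, brain >= 0.9) are oracle checks, not
clinical claims. Liver scores are computed against the *organ region*
(liver with its contained vessel and tumor), since truth labels are
disjoint but the organ anatomically contains both.

## I/O

No NIfTI or DICOM package exists in the supported dependency set, so the
package carries minimal readers/writers: NIfTI-1 (uncompressed, axis-
aligned sform, float64 volumes / int32 masks so round-trips are exact, a
JSON sidecar for the label table, NRRD accepted on read) and single-frame
explicit-VR little-endian DICOM (slices sorted by position projected on
the slice normal, rescale slope/intercept applied; mixed series, missing
spacing tags and inconsistent dimensions are errors). Anonymization
removes a documented, configurable tag list (names, IDs, birth date,
physician, institution, comments) and is idempotent; the original tool
promised only "permanent anonymization", so the tag list is a policy
decision, not derived data.

## Numerical choices and degenerate inputs

- Linear systems: direct sparse Cholesky (no iteration tolerance to tune);
  current-balance residuals are ~1e-13.
- `sigma_of_E` guards the degenerate transition `e_low == e_high`.
- With `sigma_max == sigma0` the nonlinear loop exits after one iteration
  and returns the linear solve bit-for-bit (tested).
- Contours: duplicate consecutive points are an error (the turn angle is
  undefined); reduction below 3 points is an error.
- The optimizer treats an infeasible cap as data (flagged plan), not as an
  exception, because needle-count escalation consumes it.
- Stage cache keys are md5 hashes of serialized stage inputs + parameters;
  re-running a procedure with unchanged inputs performs no recomputation.

## Known limitations

- No thermal (Joule heating) model, no transient pulse electrodynamics,
  no tetrahedral meshes, no non-parallel needle geometries.
- Tumor segmentation is manual-only (contours), by design.
- The DICOM subset excludes multi-frame/enhanced objects, sequences and
  compressed transfer syntaxes.
- Tissue parameters and electrode dimensions are nominal configuration;
  clinical use would require validated values.
- The voltage optimizer treats trajectory and electrode geometry as given;
  only voltages and (for variable arrays) needle count are optimized.
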