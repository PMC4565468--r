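# eptplan

Treatment planning for electroporation-based therapies — electrochemotherapy
(ECT) and irreversible electroporation (IRE) — of deep-seated tumors, as a
scriptable R library with a command-line interface.

Success of ECT/IRE hinges on covering the entire tumor with an electric
field above a protocol-dependent threshold. `eptplan` implements the whole
planning chain on patient-like image data:

1. **Image I/O** — read axial DICOM series into volumes (with optional
   permanent anonymization), round-trip masks as NIfTI (NRRD accepted on
   read).
2. **Segmentation** — liver on CT (distance-map core + region-based active
   contour) and MRI (region growing + adaptive thresholding + active
   contour), hepatic vessels (multiscale Frangi vesselness + local
   thresholding inside the liver), bone (thresholding), canine brain
   (per-slice morphology with central-slice detection and
   overlap-propagation).
3. **Validation** — masks become editable per-slice contours, reduced to
   20% of their points by a relevance measure
   `K(p) = beta * l1 * l2 / (l1 + l2)` (turn angle `beta`, adjacent edge
   lengths `l1`, `l2`); user-moved points are reconstructed with a
   piecewise cubic interpolant and rasterized back.
4. **Electrodes** — a catalog of commercial needle-electrode styles, placed
   as a parallel array from a two-point trajectory, with obstacle-clearance
   checking against vessels/bone.
5. **Field solver** — the conduction equation `div(sigma grad u) = 0` on the
   voxel grid (7-point finite volumes, harmonic-mean face conductivities,
   direct sparse Cholesky), with field-dependent conductivity `sigma(E)`
   (smoothstep from `sigma0` to `sigma_max`) iterated until conductivity
   stops increasing, over the successive electrode-pair pulse sequence.
6. **Planning and reporting** — cumulative coverage curves
   (dose-volume-histogram style), minimal per-pair voltages by bisection +
   per-pair descent, needle-count escalation for variable-geometry arrays,
   and an HTML/PDF treatment report (model views, voltage table, coverage
   curves, field overlays, treated volumes).

Synthetic phantoms (ellipsoidal liver with a contrast vessel and spherical
tumor, tube phantoms, a multi-slice brain stack) with ground-truth masks
make every stage testable without patient data.

## Worked example

```r
library(eptplan)

# synthetic CT case: liver, 3 mm contrast vessel, 8 mm tumor
sp <- phantom_spec(shape = c(40, 40, 24), spacing = c(2.5, 2.5, 2.5),
                   noise_sd = 0, tumor_radius = 8)
ph <- generate_abdomen_phantom(sp)

liver <- segment_liver_ct(ph$volume)
dice(liver$labels > 0, organ_region(ph$truth, "liver"))
#> [1] 1

# two parallel needles through the tumor, ECT protocol
spec <- electrode_spec_by_id("variable-single")
ctr  <- sp$tumor_center
arr  <- place_parallel_array(spec, entry = c(ctr[1], ctr[2], 0),
                             target = ctr, n = 2, spacing = 14,
                             active_length = 20)
elec <- rasterize_electrodes(arr, dim(ph$truth$labels),
                             ph$truth$spacing, ph$truth$origin)

plan <- optimize_pair_voltages(ph$truth, elec, arr,
                               protocol = pulse_protocol("ECT"),
                               delta_u = 50)
plan
#> <voltage_plan feasible: tumor coverage 1.000 at 400 V/cm>
#>   pair 1-2: 2501.56 V

plan$irreversible_volumes_mm3
#>  liver vessel  tumor
#> 1562.5    0.0 1125.0
```

The plan says: one electrode pair, 2502 V, covers 100% of the tumor at the
reversible ECT threshold (400 V/cm), while 1.56 cm^3 of liver parenchyma
and most of the 8 mm tumor sit above the irreversible (800 V/cm)
threshold. (On this noiseless phantom the liver Dice is exactly 1 at the
coarse 2.5 mm planning resolution.)
`treatment_plan_bundle()` + `render_treatment_report()` turn this into the
report document, and `run_procedure()` chains all stages from a JSON config
with content-hash caching. The same pipeline is scriptable via the
`inst/exec/eptplan` CLI (`phantom`, `import`, `anonymize`, `segment`,
`validate`, `run`, ...).

## Notes

- Units: spacing in mm, conductivity in S/m, fields in V/cm, voltages in V.
- Tissue properties and the electrode catalog are editable JSON configs in
  `inst/extdata/`; shipped values are literature-derived nominal settings.
- See the methods vignette (`vignettes/eptplan-methods.Rmd`) for the model,
  parameter choices, and known limitations.
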