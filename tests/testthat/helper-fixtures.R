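# Shared fixtures, memoized so expensive phantoms/segmentations are built
# once per test run.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

abdomen_ct <- function() fixture("abdomen_ct", function()
  generate_abdomen_phantom(phantom_spec(noise_sd = 0)))

# noise sd = 10% of the liver-background contrast (60 - (-1000) = 1060 HU)
abdomen_ct_noisy <- function() fixture("abdomen_ct_noisy", function()
  generate_abdomen_phantom(phantom_spec(noise_sd = 106, seed = 3)))

abdomen_mri <- function() fixture("abdomen_mri", function()
  generate_abdomen_phantom(phantom_spec(modality = "MRI", noise_sd = 0)))

abdomen_mri_noisy <- function() fixture("abdomen_mri_noisy", function()
  generate_abdomen_phantom(phantom_spec(modality = "MRI", noise_sd = 11,
                                        seed = 4)))

# seed voxel inside the liver but off the vessel centerline
mri_liver_seed <- function() {
  sp <- phantom_spec(modality = "MRI")
  round((sp$liver_center + c(0, 10, 0)) / sp$spacing) + 1
}

liver_ct_seg <- function() fixture("liver_ct_seg", function()
  segment_liver_ct(abdomen_ct()$volume))

# small phantom + two-needle array used by the solver/planner tests
solver_case <- function() fixture("solver_case", function() {
  sp <- phantom_spec(shape = c(40, 40, 24), spacing = c(2.5, 2.5, 2.5),
                     noise_sd = 0, tumor_radius = 8)
  ph <- generate_abdomen_phantom(sp)
  spec <- electrode_catalog()[["variable-single"]]
  ctr <- sp$tumor_center
  arr <- place_parallel_array(spec, entry = c(ctr[1], ctr[2], 0),
                              target = ctr, n = 2, spacing = 14,
                              active_length = 20)
  elec <- rasterize_electrodes(arr, dim(ph$truth$labels), ph$truth$spacing,
                               ph$truth$origin)
  list(spec = sp, truth = ph$truth, volume = ph$volume, array = arr,
       elec = elec, props = tissue_properties())
})

# coaxial-cylinder system: inner conductor radius a, outer shell radius b,
# extruded over a few slices; the analytic oracle is U / (r ln(b/a))
coax_system <- function(n = 128, a = 10, b = 55, nz = 3) {
  cx <- (n + 1) / 2
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  r2d <- matrix(sqrt((ij$i - cx)^2 + (ij$j - cx)^2), n, n)
  elec <- array(0L, c(n, n, nz))
  for (k in seq_len(nz)) {
    e <- matrix(0L, n, n)
    e[r2d <= a] <- 1L
    e[r2d >= b] <- 2L
    elec[, , k] <- e
  }
  list(elec = elec, r2d = r2d, a = a, b = b, dim = c(n, n, nz))
}

# degenerate tissue table: sigma_max == sigma0 everywhere (linear medium)
linear_props <- function() {
  p <- tissue_properties()
  for (nm in names(p)) p[[nm]]$sigma_max <- p[[nm]]$sigma0
  p
}
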