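#' Phantom specification
#'
#' Describes a synthetic test volume: grid geometry, per-tissue class mean
#' intensities, additive Gaussian noise level, and analytic geometry for the
#' abdomen preset (liver ellipsoid, cylindrical contrast vessel, spherical
#' tumor, optional bone slab). Intensities default to Hounsfield-like CT
#' values (air background -1000, liver 60, contrast vessel 150, tumor 30,
#' bone 700) or arbitrary MRI units (background 20, liver 130, vessel 200,
#' tumor 80, bone 40).
#'
#' @param shape integer length-3 grid shape.
#' @param spacing voxel spacing in mm per axis.
#' @param modality "CT" or "MRI"; selects the default intensity preset.
#' @param means named numeric vector of class mean intensities; entries
#'   override the modality preset.
#' @param noise_sd standard deviation of additive Gaussian voxel noise, in
#'   intensity units (0 = noiseless).
#' @param liver_semiaxes ellipsoid semi-axes in mm.
#' @param liver_center ellipsoid center in mm; default = field-of-view center.
#' @param vessel_radius vessel radius in mm; 0 disables the vessel.
#' @param vessel_waypoints 2-row matrix (mm) of the straight centerline's end
#'   points; default runs along x through the liver center.
#' @param tumor_center,tumor_radius spherical tumor, mm; radius 0 disables.
#' @param include_bone add a bone slab near the +x face of the volume.
#' @param bone_slab_x x-extent (mm) of the bone slab.
#' @param seed integer random seed; identical spec + seed gives identical
#'   output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 48), spacing = c(1.5, 1.5, 1.5),
                         modality = c("CT", "MRI"), means = NULL,
                         noise_sd = 0,
                         liver_semiaxes = c(35, 25, 20), liver_center = NULL,
                         vessel_radius = 3, vessel_waypoints = NULL,
                         tumor_center = NULL, tumor_radius = 10,
                         include_bone = FALSE, bone_slab_x = NULL,
                         seed = 1L) {
  modality <- match.arg(modality)
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (tumor_radius < 0 || vessel_radius < 0) stop("radii must be >= 0")
  fov <- (shape - 1) * spacing
  if (is.null(liver_center)) liver_center <- fov / 2
  if (is.null(tumor_center)) tumor_center <- liver_center + c(8, 0, 0)
  if (is.null(vessel_waypoints))
    vessel_waypoints <- rbind(c(0, liver_center[2], liver_center[3]),
                              c(fov[1], liver_center[2], liver_center[3]))
  if (is.null(bone_slab_x)) bone_slab_x <- c(fov[1] - 9, fov[1] - 3)
  defaults <- if (modality == "CT")
    c(background = -1000, liver = 60, vessel = 150, tumor = 30, bone = 700)
  else
    c(background = 20, liver = 130, vessel = 200, tumor = 80, bone = 40)
  if (!is.null(means)) defaults[names(means)] <- means
  structure(
    list(shape = shape, spacing = spacing, modality = modality,
         means = defaults, noise_sd = noise_sd,
         liver_semiaxes = as.numeric(liver_semiaxes),
         liver_center = as.numeric(liver_center),
         vessel_radius = vessel_radius,
         vessel_waypoints = vessel_waypoints,
         tumor_center = as.numeric(tumor_center), tumor_radius = tumor_radius,
         include_bone = include_bone, bone_slab_x = as.numeric(bone_slab_x),
         seed = as.integer(seed)),
    class = "phantom_spec")
}

# World coordinates (mm) of every voxel center, one matrix per axis.
voxel_coords <- function(shape, spacing, origin = c(0, 0, 0)) {
  gx <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  gy <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  gz <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  list(
    x = array(rep(gx, times = shape[2] * shape[3]), shape),
    y = array(rep(rep(gy, each = shape[1]), times = shape[3]), shape),
    z = array(rep(gz, each = shape[1] * shape[2]), shape))
}

#' Generate the abdomen phantom
#'
#' Ellipsoidal liver containing a straight cylindrical contrast vessel and a
#' spherical tumor, on an air-like background, with an optional bone slab.
#' Truth labels are disjoint: liver = 1, vessel = 2, tumor = 3, bone = 4
#' (vessel and tumor voxels are carved out of the liver label; use
#' [organ_region()] for the full liver organ).
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([image_volume()]) and
#'   `truth` ([label_mask()]).
#' @export
generate_abdomen_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  co <- voxel_coords(spec$shape, spec$spacing)
  a <- spec$liver_semiaxes; c0 <- spec$liver_center
  liver <- ((co$x - c0[1]) / a[1])^2 + ((co$y - c0[2]) / a[2])^2 +
    ((co$z - c0[3]) / a[3])^2 <= 1

  vessel <- array(FALSE, spec$shape)
  if (spec$vessel_radius > 0) {
    p0 <- spec$vessel_waypoints[1, ]; p1 <- spec$vessel_waypoints[2, ]
    d <- p1 - p0; dn <- sqrt(sum(d^2))
    if (dn == 0) stop("degenerate vessel centerline")
    d <- d / dn
    rx <- co$x - p0[1]; ry <- co$y - p0[2]; rz <- co$z - p0[3]
    t <- rx * d[1] + ry * d[2] + rz * d[3]
    dist2 <- (rx - t * d[1])^2 + (ry - t * d[2])^2 + (rz - t * d[3])^2
    vessel <- dist2 <= spec$vessel_radius^2 & t >= 0 & t <= dn & liver
  }

  tumor <- array(FALSE, spec$shape)
  if (spec$tumor_radius > 0) {
    tc <- spec$tumor_center
    tumor <- (co$x - tc[1])^2 + (co$y - tc[2])^2 + (co$z - tc[3])^2 <=
      spec$tumor_radius^2
    if (any(tumor & !liver))
      stop("geometry error: tumor extends outside the liver ellipsoid")
  }

  bone <- array(FALSE, spec$shape)
  if (spec$include_bone)
    bone <- co$x >= spec$bone_slab_x[1] & co$x <= spec$bone_slab_x[2]

  labels <- array(0L, spec$shape)
  labels[liver] <- 1L
  labels[vessel] <- 2L
  labels[tumor] <- 3L
  labels[bone] <- 4L

  m <- spec$means
  vox <- array(m[["background"]], spec$shape)
  vox[labels == 1L] <- m[["liver"]]
  vox[labels == 2L] <- m[["vessel"]]
  vox[labels == 3L] <- m[["tumor"]]
  vox[labels == 4L] <- m[["bone"]]
  if (spec$noise_sd > 0)
    vox <- vox + with_seed(spec$seed,
      array(stats::rnorm(length(vox), 0, spec$noise_sd), spec$shape))

  tab <- c(liver = 1L, vessel = 2L, tumor = 3L)
  if (spec$include_bone) tab <- c(tab, bone = 4L)
  list(volume = image_volume(vox, spec$spacing, modality = spec$modality),
       truth = label_mask(labels, spec$spacing, label_table = tab))
}

#' Union of an organ with the structures it contains
#'
#' The phantom truth labels are disjoint, but the liver organ anatomically
#' contains its vessels and the tumor; liver segmenters are scored against
#' this union.
#'
#' @param truth an `ept_mask` from a phantom generator.
#' @param organ organ name; only "liver" has contained structures.
#' @return logical array.
#' @export
organ_region <- function(truth, organ = "liver") {
  m <- mask_of(truth, organ)
  if (organ == "liver") {
    for (t in intersect(c("vessel", "tumor"), names(truth$label_table)))
      m <- m | mask_of(truth, t)
  }
  m
}

#' Generate a tube phantom
#'
#' Bright cylinder through the volume center on a darker background; the
#' vesselness-filter fixture. Labels: tube = 1, centerline voxels = 2.
#'
#' @param shape,spacing grid geometry (spacing must be isotropic for
#'   non-axis-aligned orientations).
#' @param radius tube radius, mm; must be at least one voxel.
#' @param orientation direction vector of the tube axis (normalized
#'   internally).
#' @param background,contrast background level and tube intensity increment.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return list with `volume` and `truth` (label mask with centerline).
#' @export
generate_tube_phantom <- function(shape = c(48, 48, 48), spacing = c(1, 1, 1),
                                  radius = 3, orientation = c(0, 0, 1),
                                  background = 0, contrast = 100,
                                  noise_sd = 0, seed = 1L) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  if (radius < min(spacing)) stop("radius must be at least one voxel")
  d <- orientation / sqrt(sum(orientation^2))
  # center on a voxel center so axis-aligned tubes have an exact centerline
  ci <- floor(shape / 2) + 1L
  c0 <- (ci - 1) * spacing
  co <- voxel_coords(shape, spacing)
  rx <- co$x - c0[1]; ry <- co$y - c0[2]; rz <- co$z - c0[3]
  t <- rx * d[1] + ry * d[2] + rz * d[3]
  dist2 <- pmax((rx - t * d[1])^2 + (ry - t * d[2])^2 + (rz - t * d[3])^2, 0)
  tube <- dist2 <= radius^2
  center <- dist2 <= (0.5 * min(spacing))^2 + 1e-9

  vox <- array(background, shape)
  vox[tube] <- background + contrast
  if (noise_sd > 0)
    vox <- vox + with_seed(seed,
      array(stats::rnorm(length(vox), 0, noise_sd), shape))
  labels <- array(0L, shape)
  labels[tube] <- 1L
  labels[center] <- 2L
  list(volume = image_volume(vox, spacing, modality = "MRI"),
       truth = label_mask(labels, spacing,
                          label_table = c(tube = 1L, centerline = 2L)))
}

#' Generate a brain-stack phantom
#'
#' Multi-slice MRI-like stack: an ellipsoidal brain whose cross-section is
#' maximal at the central slice and shrinks monotonically toward both ends,
#' surrounded by a bright skull shell. Labels: brain = 1, skull = 2.
#'
#' @param shape grid shape; the slice count (3rd entry) must be >= 5 and odd
#'   so the central slice is unique.
#' @param spacing voxel spacing mm.
#' @param means named intensities for background, brain, skull.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return list with `volume` and `truth`.
#' @export
generate_brain_stack_phantom <- function(shape = c(64, 64, 11),
                                         spacing = c(1.5, 1.5, 4),
                                         means = c(background = 20,
                                                   brain = 140, skull = 230),
                                         noise_sd = 0, seed = 1L) {
  shape <- as.integer(shape)
  if (shape[3] < 5) stop("brain stack needs at least 5 slices")
  if (shape[3] %% 2 == 0) stop("slice count must be odd (unique central slice)")
  spacing <- as.numeric(spacing)
  co <- voxel_coords(shape, spacing)
  fov <- (shape - 1) * spacing
  c0 <- fov / 2
  # z semi-axis deliberately exceeds the stack so end slices keep enough
  # area for adjacent-slice overlap (Dice > 0.5) while the central slice
  # remains the unique maximum
  a <- c(0.38 * fov[1], 0.32 * fov[2], 0.6 * fov[3])
  q <- ((co$x - c0[1]) / a[1])^2 + ((co$y - c0[2]) / a[2])^2 +
    ((co$z - c0[3]) / a[3])^2
  brain <- q <= 1
  skull <- q > 1 & q <= 1.45

  vox <- array(means[["background"]], shape)
  vox[brain] <- means[["brain"]]
  vox[skull] <- means[["skull"]]
  if (noise_sd > 0)
    vox <- vox + with_seed(seed,
      array(stats::rnorm(length(vox), 0, noise_sd), shape))
  labels <- array(0L, shape)
  labels[brain] <- 1L
  labels[skull] <- 2L
  list(volume = image_volume(vox, spacing, modality = "MRI"),
       truth = label_mask(labels, spacing,
                          label_table = c(brain = 1L, skull = 2L)))
}
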