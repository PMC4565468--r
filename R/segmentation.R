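# Automatic segmentation of the tissues the planner models: liver (CT and
# MRI), bone, canine brain. Hepatic vessels live in frangi.R. All algorithms
# are deterministic; parameter defaults were tuned on the package phantoms
# and are exposed as arguments, since the method families fix no numbers.

# Region-based (Chan-Vese-style) active-contour refinement, morphological
# flavor: each sweep reclassifies a one-voxel band around the current mask by
# the two-phase data term (inside mean vs local outside mean) and then
# regularizes curvature by Gaussian smoothing of the indicator. The mask can
# move at most one voxel per sweep, so it cannot jump across background gaps
# to other structures.
#' @keywords internal
active_contour_refine <- function(img, init, iterations = 30,
                                  smooth_sigma = 0.8, band = 4) {
  m <- init
  for (it in seq_len(iterations)) {
    if (!any(m)) break
    c1 <- mean(img[m])
    ring <- dilate_ball(m, band) & !m
    if (!any(ring)) break
    c2 <- mean(img[ring])
    cand <- dilate_ball(m, 1)
    mnew <- cand & ((img - c1)^2 < (img - c2)^2)
    sm <- gaussian_smooth(mnew + 0, smooth_sigma)
    mnew <- sm > 0.5
    if (identical(mnew, m)) break
    m <- mnew
  }
  fill_holes(m)
}

#' Segment the liver on CT
#'
#' Two-stage method: (1) rough localization — threshold the soft-tissue
#' intensity band, compute the Euclidean distance map of the candidate
#' foreground, and keep the connected component containing the distance-map
#' maximum (the deepest soft-tissue body); (2) refinement with a
#' region-based active contour. Returns a single connected component
#' labeled `liver`.
#'
#' @param vol CT [image_volume()].
#' @param band soft-tissue Hounsfield band used for the rough stage.
#' @param presmooth_sigma Gaussian presmoothing in mm (noise suppression).
#' @param ac_iterations,ac_smooth active-contour sweep count and indicator
#'   smoothing (voxels).
#' @return a [label_mask()] with table `c(liver = 1L)`.
#' @export
segment_liver_ct <- function(vol, band = c(-100, 300), presmooth_sigma = 2,
                             ac_iterations = 30, ac_smooth = 0.8) {
  stopifnot(inherits(vol, "ept_volume"))
  if (vol$modality != "CT") stop("segment_liver_ct requires a CT volume")
  sm <- gaussian_smooth(vol$voxels, presmooth_sigma, vol$spacing)
  cand <- sm >= band[1] & sm <= band[2]
  if (!any(cand)) stop("no liver candidate: no voxels in the soft-tissue band")
  dm <- edt_sq(cand, vol$spacing)
  rough <- component_containing(cand, which.max(dm))
  m <- active_contour_refine(sm, rough, ac_iterations, ac_smooth)
  m <- largest_component(m)
  lab <- array(0L, dim(vol$voxels)); lab[m] <- 1L
  label_mask(lab, vol$spacing, vol$origin, label_table = c(liver = 1L))
}

#' Segment the liver on MRI
#'
#' Region growing from a seed with an intensity tolerance, adaptive
#' (locally windowed) threshold cleanup, then region-based active-contour
#' refinement. The result is the connected component containing the seed.
#'
#' @param vol MRI [image_volume()].
#' @param seed voxel index `c(i, j, k)` (1-based) inside the liver.
#' @param tolerance region-growing intensity half-width; `NULL` = 25% of the
#'   seed intensity.
#' @param window_radius adaptive-threshold box half-width (voxels).
#' @param presmooth_sigma,ac_iterations,ac_smooth as in [segment_liver_ct()].
#' @return a [label_mask()] with table `c(liver = 1L)`. Warns about
#'   leakage when the grown region touches more than half the volume border.
#' @export
segment_liver_mri <- function(vol, seed, tolerance = NULL, window_radius = 6,
                              presmooth_sigma = 2, ac_iterations = 30,
                              ac_smooth = 0.8) {
  stopifnot(inherits(vol, "ept_volume"))
  if (vol$modality != "MRI") stop("segment_liver_mri requires an MRI volume")
  d <- dim(vol$voxels)
  seed <- as.integer(seed)
  if (length(seed) != 3 || any(seed < 1) || any(seed > d))
    stop("seed voxel index outside the volume")
  sm <- gaussian_smooth(vol$voxels, presmooth_sigma, vol$spacing)
  sv <- sm[seed[1], seed[2], seed[3]]
  if (is.null(tolerance)) tolerance <- 0.25 * abs(sv)
  lin <- seed[1] + (seed[2] - 1L) * d[1] + (seed[3] - 1L) * d[1] * d[2]
  grown <- array(cpp_region_grow(sm, d, lin, sv - tolerance, sv + tolerance), d)
  border <- grown
  border[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- FALSE
  nb <- 2 * (d[1] * d[2] + d[1] * d[3] + d[2] * d[3])
  if (sum(border) > 0.5 * nb)
    warning("leakage: grown region touches more than 50% of the volume border")
  if (any(grown)) {
    th <- box_stats(sm, window_radius)$mean
    cleaned <- grown & (sm >= th)
    cleaned[seed[1], seed[2], seed[3]] <- TRUE
    m <- active_contour_refine(sm, cleaned, ac_iterations, ac_smooth)
  } else m <- grown
  m[seed[1], seed[2], seed[3]] <- TRUE
  m <- component_containing(m, lin)
  lab <- array(0L, d); lab[m] <- 1L
  label_mask(lab, vol$spacing, vol$origin, label_table = c(liver = 1L))
}

#' Segment bone on CT by thresholding
#'
#' Voxels at or above the Hounsfield threshold, morphological closing, and
#' removal of components below the minimum size.
#'
#' @param vol CT [image_volume()].
#' @param threshold Hounsfield threshold (inclusive).
#' @param closing_radius closing ball radius in voxels (0 disables).
#' @param min_voxels smallest component kept.
#' @return a [label_mask()] with table `c(bone = 4L)`.
#' @export
segment_bone_ct <- function(vol, threshold = 300, closing_radius = 1,
                            min_voxels = 30) {
  stopifnot(inherits(vol, "ept_volume"))
  if (vol$modality != "CT") stop("segment_bone_ct requires a CT volume")
  m <- vol$voxels >= threshold
  if (closing_radius > 0) m <- close_ball(m, closing_radius)
  m <- drop_small_components(m, min_voxels)
  lab <- array(0L, dim(vol$voxels)); lab[m] <- 4L
  label_mask(lab, vol$spacing, vol$origin, label_table = c(bone = 4L))
}

#' Segment the canine brain from an MRI stack
#'
#' Morphology-based: per-slice thresholding and erosion, connected-component
#' analysis to find the central slice (the slice whose largest eroded
#' component has maximal area), then slice-by-slice propagation outward,
#' keeping on each neighbor slice the components that overlap the previous
#' slice's mask above `min_overlap`; propagation stops when no component
#' qualifies.
#'
#' @param vol MRI [image_volume()] with at least 5 slices.
#' @param band brain intensity band as fractions of the volume maximum
#'   (excludes dark background and the bright skull shell).
#' @param erosion_radius per-slice erosion radius in voxels.
#' @param min_overlap minimum fraction of a candidate component overlapping
#'   the previous slice's mask.
#' @param presmooth_sigma Gaussian presmoothing, mm.
#' @return a [label_mask()] with table `c(brain = 1L)`; the chosen central
#'   slice index is attached as attribute `central_slice`.
#' @export
segment_canine_brain <- function(vol, band = c(0.35, 0.8), erosion_radius = 2,
                                 min_overlap = 0.3, presmooth_sigma = 1) {
  stopifnot(inherits(vol, "ept_volume"))
  if (vol$modality != "MRI") stop("segment_canine_brain requires MRI")
  d <- dim(vol$voxels)
  if (d[3] < 5) stop("brain extraction needs at least 5 slices")
  sm <- gaussian_smooth(vol$voxels, presmooth_sigma, vol$spacing)
  mx <- max(sm)
  bin <- sm >= band[1] * mx & sm <= band[2] * mx

  slice3d <- function(k) array(bin[, , k], c(d[1], d[2], 1))
  eroded <- lapply(seq_len(d[3]), function(k)
    erode_ball(slice3d(k), erosion_radius))
  comp <- lapply(eroded, function(s) label_components(s, connect_z = FALSE))
  largest_area <- vapply(comp, function(lc) {
    n <- attr(lc, "n_components")
    if (n == 0L) 0L else max(tabulate(lc[lc > 0L], nbins = n))
  }, 0L)
  if (all(largest_area == 0L))
    stop("no brain component found on any slice")
  central <- which.max(largest_area)

  grab <- function(k, prev2d) {
    # components on eroded slice k qualifying by overlap with prev2d
    lc <- comp[[k]]
    n <- attr(lc, "n_components")
    if (n == 0L) return(NULL)
    lc2 <- array(lc, c(d[1], d[2]))
    keep <- integer(0)
    for (l in seq_len(n)) {
      cm <- lc2 == l
      if (sum(cm & prev2d) / sum(cm) >= min_overlap) keep <- c(keep, l)
    }
    if (!length(keep)) return(NULL)
    sel <- array(lc2 %in% keep, c(d[1], d[2], 1))
    dilate_ball(sel, erosion_radius)[, , 1]
  }

  out <- array(FALSE, d)
  lc <- comp[[central]]
  sizes <- tabulate(lc[lc > 0L], nbins = attr(lc, "n_components"))
  seed2d <- array(lc == which.max(sizes), c(d[1], d[2], 1))
  out[, , central] <- dilate_ball(seed2d, erosion_radius)[, , 1]
  for (dir in c(1L, -1L)) {
    prev <- out[, , central]
    k <- central + dir
    while (k >= 1L && k <= d[3]) {
      cur <- grab(k, prev)
      if (is.null(cur)) break
      out[, , k] <- cur
      prev <- cur
      k <- k + dir
    }
  }
  lab <- array(0L, d); lab[out] <- 1L
  res <- label_mask(lab, vol$spacing, vol$origin, label_table = c(brain = 1L))
  attr(res, "central_slice") <- central
  res
}
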