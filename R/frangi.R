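# Multiscale Hessian vesselness (Frangi-type) and the hepatic-vessel
# segmenter built on it.

# Shift an array along one axis with edge replication.
shift_axis <- function(arr, by, axis) {
  d <- dim(arr)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  switch(axis, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

# Second derivatives of a (pre-smoothed) volume by central differences, in
# physical units (per mm^2).
hessian_entry <- function(arr, a, b, spacing) {
  if (a == b) {
    (shift_axis(arr, 1L, a) - 2 * arr + shift_axis(arr, -1L, a)) /
      spacing[a]^2
  } else {
    g <- (shift_axis(arr, 1L, a) - shift_axis(arr, -1L, a)) / (2 * spacing[a])
    (shift_axis(g, 1L, b) - shift_axis(g, -1L, b)) / (2 * spacing[b])
  }
}

# Eigenvalues of per-voxel symmetric 3x3 matrices, vectorized trigonometric
# solution; returns the three eigenvalue arrays sorted by absolute value.
sym3_eigen_absorted <- function(hxx, hyy, hzz, hxy, hxz, hyz) {
  q <- (hxx + hyy + hzz) / 3
  p1 <- hxy^2 + hxz^2 + hyz^2
  p2 <- (hxx - q)^2 + (hyy - q)^2 + (hzz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  safe_p <- ifelse(p > 0, p, 1)
  a <- (hxx - q) / safe_p; b <- hxy / safe_p; c3 <- hxz / safe_p
  e <- (hyy - q) / safe_p; f <- hyz / safe_p; i3 <- (hzz - q) / safe_p
  detB <- a * (e * i3 - f^2) - b * (b * i3 - f * c3) + c3 * (b * f - e * c3)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  # compare-exchange network on |lambda|
  sw <- abs(l1) > abs(l2)
  t <- l1[sw]; l1[sw] <- l2[sw]; l2[sw] <- t
  sw <- abs(l2) > abs(l3)
  t <- l2[sw]; l2[sw] <- l3[sw]; l3[sw] <- t
  sw <- abs(l1) > abs(l2)
  t <- l1[sw]; l1[sw] <- l2[sw]; l2[sw] <- t
  list(l1 = l1, l2 = l2, l3 = l3)
}

#' Multiscale Frangi vesselness filter
#'
#' Per scale: Gaussian smoothing at sigma, scale-normalized Hessian (factor
#' sigma^2), eigenvalues ordered `|l1| <= |l2| <= |l3|`, and the tubularity
#' response built from the plate/blob ratio `RA = |l2|/|l3|`, the blob ratio
#' `RB = |l1|/sqrt(|l2 l3|)` and second-order structureness
#' `S = sqrt(l1^2+l2^2+l3^2)`:
#' `(1-exp(-RA^2/2a^2)) * exp(-RB^2/2b^2) * (1-exp(-S^2/2c^2))`,
#' zero where `l2` or `l3` has the wrong sign for the requested polarity.
#' The final response is the voxelwise maximum over scales and lies in
#' `[0, 1]`.
#'
#' @param vol an [image_volume()].
#' @param scales Gaussian scales in mm, ascending, positive.
#' @param alpha,beta Frangi sensitivity parameters (> 0).
#' @param c structure-noise scale; `NULL` = half the maximum structureness at
#'   each scale (the usual auto setting).
#' @param bright `TRUE` for bright tubes on dark background.
#' @return 3D numeric response array in `[0, 1]`.
#' @export
frangi_vesselness <- function(vol, scales = c(1, 2, 3), alpha = 0.5,
                              beta = 0.5, c = NULL, bright = TRUE) {
  stopifnot(inherits(vol, "ept_volume"))
  scales <- as.numeric(scales)
  if (any(scales <= 0)) stop("scales must be positive")
  if (is.unsorted(scales)) stop("scales must be ascending")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  out <- array(0, dim(vol$voxels))
  for (s in scales) {
    sm <- gaussian_smooth(vol$voxels, s, vol$spacing)
    hxx <- s^2 * hessian_entry(sm, 1, 1, vol$spacing)
    hyy <- s^2 * hessian_entry(sm, 2, 2, vol$spacing)
    hzz <- s^2 * hessian_entry(sm, 3, 3, vol$spacing)
    hxy <- s^2 * hessian_entry(sm, 1, 2, vol$spacing)
    hxz <- s^2 * hessian_entry(sm, 1, 3, vol$spacing)
    hyz <- s^2 * hessian_entry(sm, 2, 3, vol$spacing)
    ev <- sym3_eigen_absorted(hxx, hyy, hzz, hxy, hxz, hyz)
    S2 <- ev$l1^2 + ev$l2^2 + ev$l3^2
    cs <- if (is.null(c)) sqrt(max(S2)) / 2 else c
    if (cs <= 0) next  # flat volume at this scale: no structure anywhere
    denom23 <- abs(ev$l2 * ev$l3)
    RA2 <- ifelse(ev$l3 != 0, (ev$l2 / ev$l3)^2, 0)
    RB2 <- ifelse(denom23 > 0, ev$l1^2 / denom23, 0)
    v <- (1 - exp(-RA2 / (2 * alpha^2))) * exp(-RB2 / (2 * beta^2)) *
      (1 - exp(-S2 / (2 * cs^2)))
    wrong <- if (bright) (ev$l2 > 0 | ev$l3 > 0) else (ev$l2 < 0 | ev$l3 < 0)
    v[wrong | ev$l3 == 0] <- 0
    out <- pmax(out, v)
  }
  out
}

#' Segment hepatic vessels inside a liver mask
#'
#' Vesselness is computed inside the liver only (outside voxels are replaced
#' by the median liver intensity so the organ boundary produces no
#' response). Seed voxels are vesselness responses above a high quantile
#' (and above an absolute floor); the final mask collects voxels in a
#' neighborhood of the seeds whose intensity exceeds a locally computed
#' threshold (window mean + k * window sd). The result is always a subset
#' of the liver mask.
#'
#' @param vol an [image_volume()].
#' @param liver liver [label_mask()] (any nonzero label counts).
#' @param scales,alpha,beta,c passed to [frangi_vesselness()].
#' @param seed_quantile quantile of the in-liver response used for seeds.
#' @param response_floor absolute minimum seed response; if no voxel reaches
#'   it the result is empty (vessel-free livers stay vessel-free).
#' @param neighborhood_radius dilation radius (voxels) around seeds.
#' @param window_radius,k local-threshold box half-width and sd multiplier.
#' @param min_contrast minimum intensity excess of a seed over the median
#'   liver intensity; rejects tube-shaped responses at parenchyma level
#'   (e.g. the rim of a dark lesion) that are not contrast-filled vessels.
#'   Intensity units (default suits CT HU with contrast).
#' @return a [label_mask()] with table `c(vessel = 2L)`.
#' @export
segment_vessels <- function(vol, liver, scales = c(1, 2, 3), alpha = 0.5,
                            beta = 0.5, c = NULL, seed_quantile = 0.99,
                            response_floor = 0.1, neighborhood_radius = 2,
                            window_radius = 4, k = 0.25, min_contrast = 30) {
  stopifnot(inherits(vol, "ept_volume"), inherits(liver, "ept_mask"))
  check_same_grid(vol, liver)
  lm <- liver$labels > 0L
  if (!any(lm)) stop("empty liver mask")
  vox <- vol$voxels
  med <- stats::median(vox[lm])
  vox[!lm] <- med
  vvol <- image_volume(vox, vol$spacing, vol$origin, modality = vol$modality)
  resp <- frangi_vesselness(vvol, scales, alpha, beta, c)
  resp[!lm] <- 0
  thr <- max(stats::quantile(resp[lm], seed_quantile), response_floor)
  seeds <- resp >= thr & resp >= response_floor & lm &
    vol$voxels >= med + min_contrast
  d <- dim(vox)
  if (!any(seeds)) {
    lab <- array(0L, d)
    return(label_mask(lab, vol$spacing, vol$origin,
                      label_table = c(vessel = 2L)))
  }
  nb <- dilate_ball(seeds, neighborhood_radius)
  st <- box_stats(vox, window_radius, want_sd = TRUE)
  m <- (nb & (vox >= st$mean + k * st$sd) & lm) | seeds
  lab <- array(0L, d); lab[m] <- 2L
  label_mask(lab, vol$spacing, vol$origin, label_table = c(vessel = 2L))
}
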