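# Low-level grid operations shared by the segmentation and modeling code.
# All functions take plain 3D arrays; geometry-aware wrappers live with the
# callers.

# Move `axis` to the first dimension and flatten the rest into columns.
axis_first <- function(arr, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  list(m = matrix(a, nrow = dim(a)[1]), dims = dim(a), perm = perm)
}

axis_restore <- function(m, af) {
  a <- array(m, dim = af$dims)
  aperm(a, order(af$perm))
}

# Separable Gaussian smoothing; sigma in mm, converted per axis via spacing.
#' @keywords internal
gaussian_smooth <- function(arr, sigma_mm, spacing = c(1, 1, 1)) {
  out <- arr
  for (axis in 1:3) {
    s <- sigma_mm / spacing[axis]
    if (s < 1e-6) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-((-r:r)^2) / (2 * s^2))
    w <- w / sum(w)
    af <- axis_first(out, axis)
    n <- nrow(af$m)
    padded <- rbind(af$m[rep(1L, r), , drop = FALSE], af$m,
                    af$m[rep(n, r), , drop = FALSE])
    f <- stats::filter(padded, w, sides = 2)
    af$m <- as.matrix(f[(r + 1):(r + n), , drop = FALSE])
    out <- axis_restore(af$m, af)
  }
  out
}

# Clamped-window box mean (and optionally sd) via running sums, separable.
#' @keywords internal
box_stats <- function(arr, radius, want_sd = FALSE) {
  box_sum <- function(a) {
    for (axis in 1:3) {
      af <- axis_first(a, axis)
      n <- nrow(af$m)
      cs <- apply(af$m, 2, cumsum)
      cs <- rbind(0, cs)
      hi <- pmin(1:n + radius, n) + 1L
      lo <- pmax(1:n - radius, 1L)
      af$m <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
      a <- axis_restore(af$m, af)
    }
    a
  }
  d <- dim(arr)
  len1d <- function(n) pmin(1:n + radius, n) - pmax(1:n - radius, 1L) + 1L
  counts <- outer(outer(len1d(d[1]), len1d(d[2])), len1d(d[3]))
  dim(counts) <- d
  mu <- box_sum(arr) / counts
  if (!want_sd) return(list(mean = mu))
  ex2 <- box_sum(arr^2) / counts
  v <- pmax(ex2 - mu^2, 0)
  list(mean = mu, sd = sqrt(v))
}

# Squared Euclidean distance of foreground voxels to nearest background, mm^2.
#' @keywords internal
edt_sq <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  out <- cpp_edt_sq(as.logical(mask), as.integer(d), as.numeric(spacing))
  array(out, dim = d)
}

#' @keywords internal
distance_map <- function(mask, spacing = c(1, 1, 1)) sqrt(edt_sq(mask, spacing))

# Binary morphology with a Euclidean ball of radius r (voxel units by default).
#' @keywords internal
dilate_ball <- function(mask, r, spacing = c(1, 1, 1)) {
  if (r <= 0) return(mask)
  mask | (edt_sq(!mask, spacing) <= r^2 + 1e-9)
}

#' @keywords internal
erode_ball <- function(mask, r, spacing = c(1, 1, 1)) {
  if (r <= 0) return(mask)
  mask & (edt_sq(mask, spacing) > r^2 + 1e-9)
}

#' @keywords internal
close_ball <- function(mask, r, spacing = c(1, 1, 1)) {
  erode_ball(dilate_ball(mask, r, spacing), r, spacing)
}

# Connected components; 6-connectivity (or per-slice 4-connectivity).
#' @keywords internal
label_components <- function(mask, connect_z = TRUE) {
  d <- dim(mask)
  lab <- cpp_label_components(as.logical(mask), as.integer(d), connect_z)
  n <- attr(lab, "n_components")
  lab <- array(as.integer(lab), dim = d)
  attr(lab, "n_components") <- n
  lab
}

#' @keywords internal
largest_component <- function(mask, connect_z = TRUE) {
  lab <- label_components(mask, connect_z)
  n <- attr(lab, "n_components")
  if (n == 0L) return(array(FALSE, dim(mask)))
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  lab == which.max(sizes)
}

# Component of `mask` containing linear voxel index `idx` (must be foreground).
#' @keywords internal
component_containing <- function(mask, idx, connect_z = TRUE) {
  lab <- label_components(mask, connect_z)
  l <- lab[idx]
  if (l == 0L) return(array(FALSE, dim(mask)))
  lab == l
}

# Fill interior cavities: background components not touching the array
# border. Axes of extent 1 contribute no border (a single-slice array is
# filled in-plane, not declared all-border).
#' @keywords internal
fill_holes <- function(mask) {
  lab <- label_components(!mask)
  d <- dim(mask)
  border <- integer(0)
  if (d[1] > 1) border <- c(border, lab[1, , ], lab[d[1], , ])
  if (d[2] > 1) border <- c(border, lab[, 1, ], lab[, d[2], ])
  if (d[3] > 1) border <- c(border, lab[, , 1], lab[, , d[3]])
  border <- unique(border[border > 0L])
  mask | (lab > 0L & !(lab %in% border))
}

# Remove connected components smaller than min_voxels.
#' @keywords internal
drop_small_components <- function(mask, min_voxels, connect_z = TRUE) {
  lab <- label_components(mask, connect_z)
  n <- attr(lab, "n_components")
  if (n == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim(mask))
}
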