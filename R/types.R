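#' Image volume container
#'
#' A 3D scalar grid with physical geometry. Voxel values are Hounsfield units
#' for CT and arbitrary units for MRI. Indexing is `[i, j, k]` with `i` the
#' fastest-varying in-plane axis; the world position of voxel `(i, j, k)`
#' (1-based) is `origin + (c(i, j, k) - 1) * spacing` along the direction
#' cosines (phantom and I/O code only produce axis-aligned volumes).
#'
#' @param voxels 3D numeric array, all values finite, dims at least (8, 8, 3).
#' @param spacing numeric length-3, voxel edge length per axis in mm, > 0.
#' @param origin numeric length-3, world position (mm) of the first voxel center.
#' @param modality "CT" or "MRI".
#' @param direction 3x3 direction-cosine matrix (columns = world direction of
#'   each index axis); defaults to identity.
#' @return an object of class `ept_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         modality = c("CT", "MRI"), direction = diag(3)) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (any(dim(voxels) < c(8L, 8L, 3L)))
    stop("volume shape must be at least (8, 8, 3)")
  if (!all(is.finite(voxels))) stop("all voxel values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers (mm)")
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         modality = modality, direction = direction),
    class = "ept_volume")
}

#' Label mask container
#'
#' Integer tissue labels on the same grid as a parent [image_volume()].
#' Label 0 is background and never appears in the label table.
#'
#' @param labels 3D integer array.
#' @param spacing,origin grid geometry, as in [image_volume()].
#' @param label_table named integer vector mapping tissue name to label value;
#'   every nonzero label present in `labels` must appear in the table.
#' @return an object of class `ept_mask`.
#' @export
label_mask <- function(labels, spacing, origin = c(0, 0, 0),
                       label_table = c(foreground = 1L)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  label_table <- stats::setNames(as.integer(label_table), names(label_table))
  if (is.null(names(label_table)) || any(!nzchar(names(label_table))))
    stop("label_table must be a named integer vector")
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0L]
  missing <- setdiff(present, label_table)
  if (length(missing))
    stop("labels present but not in label table: ", paste(missing, collapse = ", "))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be positive")
  structure(
    list(labels = labels, spacing = spacing, origin = as.numeric(origin),
         label_table = label_table),
    class = "ept_mask")
}

#' @export
print.ept_volume <- function(x, ...) {
  cat(sprintf("<ept_volume %s %s, spacing %s mm, range [%.4g, %.4g]>\n",
              x$modality, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.ept_mask <- function(x, ...) {
  counts <- vapply(x$label_table, function(l) sum(x$labels == l), integer(1))
  cat(sprintf("<ept_mask %s: %s>\n", paste(dim(x$labels), collapse = "x"),
              paste(sprintf("%s=%d (%d vox)", names(x$label_table),
                            x$label_table, counts), collapse = ", ")))
  invisible(x)
}

#' Binary mask for one tissue
#'
#' @param mask an `ept_mask`.
#' @param tissue tissue name in the label table.
#' @return logical 3D array.
#' @export
mask_of <- function(mask, tissue) {
  stopifnot(inherits(mask, "ept_mask"))
  if (!tissue %in% names(mask$label_table))
    stop("unknown tissue: ", tissue)
  mask$labels == mask$label_table[[tissue]]
}

#' Dice overlap coefficient between two binary arrays
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#' @param a,b logical arrays of identical shape.
#' @return numeric scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' @keywords internal
check_same_grid <- function(a, b, what = "inputs") {
  da <- if (inherits(a, "ept_volume")) dim(a$voxels) else dim(a$labels)
  db <- if (inherits(b, "ept_volume")) dim(b$voxels) else dim(b$labels)
  if (!identical(da, db)) stop(what, " are on different grids")
  invisible(TRUE)
}

# Run expr with a private RNG state seeded by `seed`, restoring the caller's.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
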