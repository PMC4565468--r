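# Electrode catalog, parallel-array placement from a two-point trajectory,
# obstacle clearance checking, and rasterization of active segments into
# boundary-condition voxels.

#' Load the electrode catalog
#'
#' One spec per commercially available style (hexagonal 7-needle, linear
#' pair, finger electrodes with axial / perpendicular needles, and
#' variable-geometry single needles). Dimensions ship in an editable JSON
#' config; they are nominal, not manufacturer-verified.
#'
#' @param path catalog JSON; default = the packaged catalog.
#' @return named list of electrode specs (class `electrode_spec`).
#' @export
electrode_catalog <- function(path = system.file("extdata",
                                                 "electrode_catalog.json",
                                                 package = "eptplan")) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed catalog file: ",
                                           conditionMessage(e)))
  if (is.null(doc$electrodes)) stop("malformed catalog file: no electrodes")
  specs <- lapply(doc$electrodes, function(e) {
    s <- list(id = e$id, style = e$style,
              diameter = as.numeric(e$needle_diameter_mm),
              active_lengths = as.numeric(unlist(e$active_lengths_mm)),
              default_active_length = as.numeric(e$default_active_length_mm),
              offsets = if (length(e$offsets_mm))
                do.call(rbind, lapply(e$offsets_mm, unlist)) else
                  matrix(0, 0, 2),
              max_voltage = as.numeric(e$max_voltage_V))
    if (s$diameter <= 0) stop("catalog: diameter must be > 0 for ", s$id)
    if (any(s$active_lengths <= 0))
      stop("catalog: active lengths must be > 0 for ", s$id)
    if (s$style != "variable" && nrow(s$offsets) < 2)
      stop("catalog: fixed-geometry style needs >= 2 offsets for ", s$id)
    class(s) <- "electrode_spec"
    s
  })
  stats::setNames(specs, vapply(specs, function(s) s$id, ""))
}

#' @rdname electrode_catalog
#' @param id electrode spec id.
#' @export
electrode_spec_by_id <- function(id, path = system.file(
                                   "extdata", "electrode_catalog.json",
                                   package = "eptplan")) {
  cat_ <- electrode_catalog(path)
  if (!id %in% names(cat_)) stop("unknown electrode id: ", id)
  cat_[[id]]
}

# orthonormal in-plane basis (u, v) perpendicular to unit vector d
plane_basis <- function(d) {
  e <- if (abs(d[1]) <= abs(d[2]) && abs(d[1]) <= abs(d[3])) c(1, 0, 0)
       else if (abs(d[2]) <= abs(d[3])) c(0, 1, 0) else c(0, 0, 1)
  u <- c(d[2] * e[3] - d[3] * e[2], d[3] * e[1] - d[1] * e[3],
         d[1] * e[2] - d[2] * e[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

#' Place a parallel needle array from a two-point trajectory
#'
#' The trajectory runs from `entry` to `target` (mm, world space); all
#' needles are parallel to it. Needle tips are laid out on the plane through
#' `target` perpendicular to the trajectory: fixed-geometry styles use the
#' catalog offsets, the variable style a symmetric in-plane row with the
#' given spacing. The pulse-pair sequence is all adjacent pairs for
#' linear/variable rows and the conventional 12-pair sequence
#' (center-outer then outer ring) for the hexagonal style.
#'
#' @param spec an `electrode_spec` from [electrode_catalog()].
#' @param entry,target trajectory points, mm; must differ.
#' @param n needle count (variable style only; ignored for fixed styles).
#' @param spacing inter-needle spacing for the variable style, mm.
#' @param active_length active-segment length, mm; must be one of the
#'   spec's allowed lengths. `NULL` = spec default.
#' @return an object of class `electrode_array`.
#' @export
place_parallel_array <- function(spec, entry, target, n = 2, spacing = 10,
                                 active_length = NULL) {
  stopifnot(inherits(spec, "electrode_spec"))
  entry <- as.numeric(entry); target <- as.numeric(target)
  d <- target - entry
  dn <- sqrt(sum(d^2))
  if (dn < 1e-12) stop("zero-length trajectory")
  d <- d / dn
  if (is.null(active_length)) active_length <- spec$default_active_length
  if (!any(abs(spec$active_lengths - active_length) < 1e-9))
    stop("active length ", active_length, " not offered by spec ", spec$id)
  b <- plane_basis(d)
  if (spec$style == "variable") {
    if (n < 2) stop("variable-geometry arrays need at least 2 needles")
    off_u <- (seq_len(n) - (n + 1) / 2) * spacing
    offsets <- cbind(off_u, 0)
  } else {
    offsets <- spec$offsets
    n <- nrow(offsets)
  }
  tips <- t(vapply(seq_len(n), function(i)
    target + offsets[i, 1] * b$u + offsets[i, 2] * b$v, numeric(3)))
  if (spec$style == "hexagonal") {
    outer_ring <- 2:7
    pairs <- rbind(cbind(1L, outer_ring),
                   cbind(outer_ring, c(outer_ring[-1], 2L)))
  } else {
    pairs <- cbind(seq_len(n - 1), 2:n)
  }
  structure(list(spec = spec, direction = d, entry = entry, target = target,
                 tips = tips, active_length = active_length,
                 insertion_depth = dn, pairs = unname(pairs)),
            class = "electrode_array")
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("<electrode_array %s: %d needles, %d pairs, active %g mm>\n",
              x$spec$id, nrow(x$tips), nrow(x$pairs), x$active_length))
  invisible(x)
}

#' Check needle trajectories against obstacle masks
#'
#' Samples each needle's insertion path (from its entry plane to its tip)
#' at sub-voxel steps and evaluates the distance transform of every
#' obstacle mask along the path. Obstacles approached closer than `margin`
#' produce violations.
#'
#' @param array an `electrode_array`.
#' @param obstacles named list of [label_mask()] (any nonzero label is the
#'   obstacle).
#' @param margin clearance margin, mm.
#' @return data frame with one row per (needle, obstacle): closest approach
#'   in mm and whether it violates the margin.
#' @export
check_trajectory_clearance <- function(array, obstacles, margin = 0) {
  stopifnot(inherits(array, "electrode_array"))
  if (!length(obstacles))
    return(data.frame(needle = integer(0), obstacle = character(0),
                      distance_mm = numeric(0), violation = logical(0)))
  rows <- list()
  for (ob_name in names(obstacles)) {
    ob <- obstacles[[ob_name]]
    stopifnot(inherits(ob, "ept_mask"))
    if (!any(ob$labels > 0L)) next
    dmap <- sqrt(edt_sq(ob$labels == 0L, ob$spacing))
    d <- dim(ob$labels)
    step <- 0.5 * min(ob$spacing)
    for (i in seq_len(nrow(array$tips))) {
      tip <- array$tips[i, ]
      start <- tip - array$direction * array$insertion_depth
      ts <- seq(0, array$insertion_depth, by = step)
      pts <- outer(ts, array$direction) +
        matrix(start, length(ts), 3, byrow = TRUE)
      ijk <- sweep(sweep(pts, 2, ob$origin), 2, ob$spacing, "/") + 1
      ijk <- round(ijk)
      keep <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 &
        ijk[, 2] <= d[2] & ijk[, 3] >= 1 & ijk[, 3] <= d[3]
      if (!any(keep)) next
      dist <- min(dmap[ijk[keep, , drop = FALSE]])
      rows[[length(rows) + 1]] <- data.frame(
        needle = i, obstacle = ob_name, distance_mm = dist,
        violation = dist < margin)
    }
  }
  if (!length(rows))
    return(data.frame(needle = integer(0), obstacle = character(0),
                      distance_mm = numeric(0), violation = logical(0)))
  do.call(rbind, rows)
}

#' Rasterize electrode active segments into a boundary label grid
#'
#' Voxels whose centers lie within the needle radius of a needle's active
#' segment (the `active_length` mm of shaft ending at the tip) receive that
#' needle's 1-based id; the insulated shaft above the active segment
#' contributes nothing. On grids coarser than the needle diameter the
#' capture radius is floored at 0.75 of the largest voxel edge (a needle axis can pass up to ~0.71 voxel edges from every cell center) so that every
#' needle is represented (documented deviation from pure center-inclusion).
#'
#' @param array an `electrode_array`.
#' @param dim grid shape; @param spacing,origin grid geometry (mm).
#' @return integer array: 0 = tissue, i = needle i conductor voxels.
#' @export
rasterize_electrodes <- function(array, dim, spacing, origin = c(0, 0, 0)) {
  stopifnot(inherits(array, "electrode_array"))
  lab <- array(0L, dim)
  r <- max(array$spec$diameter / 2, 0.75 * max(spacing))
  upper <- origin + (dim - 1) * spacing
  for (i in seq_len(nrow(array$tips))) {
    p1 <- array$tips[i, ]
    p0 <- p1 - array$direction * array$active_length
    if (any(p0 < origin - 1e-9) || any(p0 > upper + 1e-9) ||
        any(p1 < origin - 1e-9) || any(p1 > upper + 1e-9))
      stop("needle ", i, " active segment extends outside the grid")
    lo <- pmax(floor((pmin(p0, p1) - r - origin) / spacing) + 1, 1)
    hi <- pmin(ceiling((pmax(p0, p1) + r - origin) / spacing) + 1, dim)
    gx <- origin[1] + (lo[1]:hi[1] - 1) * spacing[1]
    gy <- origin[2] + (lo[2]:hi[2] - 1) * spacing[2]
    gz <- origin[3] + (lo[3]:hi[3] - 1) * spacing[3]
    sub <- c(length(gx), length(gy), length(gz))
    X <- array(rep(gx, times = sub[2] * sub[3]), sub)
    Y <- array(rep(rep(gy, each = sub[1]), times = sub[3]), sub)
    Z <- array(rep(gz, each = sub[1] * sub[2]), sub)
    vx <- X - p0[1]; vy <- Y - p0[2]; vz <- Z - p0[3]
    dvec <- p1 - p0; L <- sqrt(sum(dvec^2)); dn <- dvec / L
    t <- vx * dn[1] + vy * dn[2] + vz * dn[3]
    tc <- pmin(pmax(t, 0), L)
    dist2 <- (vx - tc * dn[1])^2 + (vy - tc * dn[2])^2 + (vz - tc * dn[3])^2
    inside <- dist2 <= r^2 + 1e-12
    lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]][inside] <- i
  }
  lab
}
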