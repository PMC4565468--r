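# Mask <-> contour machinery for segmentation validation: per-slice contour
# extraction, relevance-based point reduction, user edits with piecewise
# cubic reconstruction, and rasterization back to masks.
#
# Contour points are continuous pixel coordinates (row, col), 0-based, on
# the slice plane; the closing edge (last -> first) is implicit.

#' Slice contour constructor
#'
#' @param points n x 2 numeric matrix of (row, col) coordinates, ordered,
#'   first point not repeated at the end.
#' @param slice 1-based slice index.
#' @param flags per-point provenance: "original", "user-moved" or
#'   "synthetic".
#' @param axis slice plane axis (3 = axial).
#' @param original_count point count before any reduction.
#' @param retained_percent current retention level in (0, 100].
#' @return object of class `slice_contour`.
#' @export
slice_contour <- function(points, slice, flags = NULL, axis = 3L,
                          original_count = nrow(points),
                          retained_percent = 100) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("a contour needs at least 3 points")
  if (ncol(points) != 2) stop("points must be an n x 2 matrix")
  if (is.null(flags)) flags <- rep("original", nrow(points))
  if (length(flags) != nrow(points)) stop("one flag per point required")
  if (!all(flags %in% c("original", "user-moved", "synthetic")))
    stop("invalid flag value")
  if (retained_percent <= 0 || retained_percent > 100)
    stop("retained_percent must be in (0, 100]")
  structure(list(points = unname(points), slice = as.integer(slice),
                 axis = as.integer(axis), flags = flags,
                 original_count = as.integer(original_count),
                 retained_percent = retained_percent),
            class = "slice_contour")
}

#' @export
print.slice_contour <- function(x, ...) {
  cat(sprintf("<slice_contour slice %d: %d pts (%g%% of %d), %d user-moved>\n",
              x$slice, nrow(x$points), x$retained_percent, x$original_count,
              sum(x$flags == "user-moved")))
  invisible(x)
}

# signed area (shoelace) in the (col, row) plane; > 0 = counterclockwise
shoelace <- function(pts) {
  x <- pts[, 2]; y <- pts[, 1]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# even-odd point-in-polygon (pts closed implicitly)
point_in_poly <- function(p, pts) {
  x <- pts[, 2]; y <- pts[, 1]
  n <- nrow(pts)
  j <- c(n, seq_len(n - 1))
  cross <- ((y > p[1]) != (y[j] > p[1])) &
    (p[2] < (x[j] - x) * (p[1] - y) / (y[j] - y) + x)
  sum(cross) %% 2 == 1
}

# do segments (p1,p2) and (p3,p4) properly intersect?
segs_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[2] - a[2]) * (c[1] - a[1]) -
    (b[1] - a[1]) * (c[2] - a[2])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

contour_is_simple <- function(pts) {
  n <- nrow(pts)
  seg <- function(i) list(pts[i, ], pts[if (i == n) 1L else i + 1L, ])
  for (i in seq_len(n - 1)) {
    si <- seg(i)
    for (j in (i + 1):n) {
      if (j == i || abs(i - j) == 1 || (i == 1 && j == n)) next
      sj <- seg(j)
      if (segs_intersect(si[[1]], si[[2]], sj[[1]], sj[[2]])) return(FALSE)
    }
  }
  TRUE
}

#' Extract per-slice contours of a label
#'
#' Marching-squares boundary of the label at the 0.5 iso-level on each
#' slice, one contour per connected 2D region, ordered counterclockwise;
#' holes are ignored.
#'
#' @param mask a [label_mask()].
#' @param label label value or tissue name.
#' @return list of [slice_contour()]; empty if the label is absent.
#' @export
extract_slice_contours <- function(mask, label) {
  stopifnot(inherits(mask, "ept_mask"))
  if (is.character(label)) {
    if (!label %in% names(mask$label_table)) return(list())
    label <- mask$label_table[[label]]
  }
  d <- dim(mask$labels)
  out <- list()
  for (k in seq_len(d[3])) {
    sl <- (mask$labels[, , k] == label) + 0
    if (!any(sl > 0)) next
    padded <- matrix(0, d[1] + 2, d[2] + 2)
    padded[2:(d[1] + 1), 2:(d[2] + 1)] <- sl
    # pixel (i, j) center sits at (row, col) = (i-1, j-1)
    cl <- grDevices::contourLines(x = seq(-1, d[1]) , y = seq(-1, d[2]),
                                  z = padded, levels = 0.5)
    if (!length(cl)) next
    polys <- lapply(cl, function(cc) {
      pts <- cbind(cc$x, cc$y)
      if (nrow(pts) > 1 &&
          all(abs(pts[1, ] - pts[nrow(pts), ]) < 1e-9))
        pts <- pts[-nrow(pts), , drop = FALSE]
      pts
    })
    polys <- polys[vapply(polys, nrow, 0L) >= 3]
    if (!length(polys)) next
    # drop holes: a contour whose first vertex lies inside another contour
    is_hole <- vapply(seq_along(polys), function(i) {
      any(vapply(seq_along(polys), function(j)
        j != i && point_in_poly(polys[[i]][1, ], polys[[j]]), TRUE))
    }, TRUE)
    polys <- polys[!is_hole]
    for (pts in polys) {
      if (shoelace(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), ]
      out[[length(out) + 1]] <- slice_contour(pts, slice = k)
    }
  }
  out
}

#' Per-point influence scores of a contour
#'
#' Relevance measure `K(p) = beta * l1 * l2 / (l1 + l2)` on the closed
#' cycle, where `beta` is the turn angle at `p` (radians, 0 for collinear
#' points) and `l1`, `l2` the adjacent edge lengths. Low influence = safe
#' to delete.
#'
#' @param contour a [slice_contour()] (or bare point matrix).
#' @return nonnegative numeric vector, one score per point.
#' @export
point_influence <- function(contour) {
  pts <- if (inherits(contour, "slice_contour")) contour$points else contour
  n <- nrow(pts)
  if (n < 3) stop("a contour needs at least 3 points")
  prv <- pts[c(n, seq_len(n - 1)), , drop = FALSE]
  nxt <- pts[c(seq_len(n)[-1], 1), , drop = FALSE]
  e1 <- pts - prv; e2 <- nxt - pts
  l1 <- sqrt(rowSums(e1^2)); l2 <- sqrt(rowSums(e2^2))
  if (any(l1 < 1e-12)) stop("duplicate consecutive points in contour")
  cosb <- pmin(pmax(rowSums(e1 * e2) / (l1 * l2), -1), 1)
  beta <- acos(cosb)
  beta * l1 * l2 / (l1 + l2)
}

#' Simplify a contour by iterative least-influence deletion
#'
#' Deletes the minimum-influence point (ties: lowest index), recomputing the
#' influence of its two neighbors, until `ceiling(percent/100 * n)` points
#' remain. Retained points are a subset of the input, order and flags
#' preserved; user-moved points are never deleted.
#'
#' @param contour a [slice_contour()].
#' @param percent target retention in percent of the *current* point count.
#' @return the simplified [slice_contour()].
#' @export
simplify_contour <- function(contour, percent = 20) {
  stopifnot(inherits(contour, "slice_contour"))
  n <- nrow(contour$points)
  target <- ceiling(percent / 100 * n)
  if (target < 3)
    stop("retention percent leaves fewer than 3 points")
  keep <- seq_len(n)
  pts <- contour$points
  protected <- contour$flags == "user-moved"
  infl <- point_influence(pts)
  while (length(keep) > target) {
    cand <- infl
    cand[protected[keep]] <- Inf
    i <- which.min(cand)  # which.min takes the first (lowest index) on ties
    if (!is.finite(cand[i])) break  # everything protected
    keep <- keep[-i]
    pts <- contour$points[keep, , drop = FALSE]
    infl <- infl[-i]
    m <- length(keep)
    for (nb in unique(c((i - 2) %% m + 1, (i - 1) %% m + 1))) {
      # recompute influence of the two neighbors of the removed point
      idx <- c((nb - 2) %% m + 1, nb, nb %% m + 1)
      infl[nb] <- point_influence(pts[idx, , drop = FALSE])[2]
    }
  }
  slice_contour(contour$points[keep, , drop = FALSE], contour$slice,
                flags = contour$flags[keep], axis = contour$axis,
                original_count = contour$original_count,
                retained_percent = percent)
}

# closed parametric natural-cubic sampling through `knots` (k x 2), step in
# pixels; returns sampled points including the knots exactly
sample_cubic_through <- function(knots, step = 1, periodic = FALSE) {
  k <- nrow(knots)
  seg <- sqrt(rowSums((knots[-1, , drop = FALSE] -
                       knots[-k, , drop = FALSE])^2))
  t <- c(0, cumsum(seg))
  if (periodic) {
    # repeat first knot at the end for a closed curve
    knots <- rbind(knots, knots[1, ])
    t <- c(t, t[k] + sqrt(sum((knots[k + 1, ] - knots[k, ])^2)))
    k <- k + 1
  }
  tout <- sort(unique(c(t, seq(0, t[k], by = step))))
  method <- if (periodic) "periodic" else "natural"
  sx <- stats::spline(t, knots[, 1], xout = tout, method = method)$y
  sy <- stats::spline(t, knots[, 2], xout = tout, method = method)$y
  # snap parameter values that coincide with knots to the knot coordinates
  isknot <- tout %in% t
  sx[isknot] <- knots[match(tout[isknot], t), 1]
  sy[isknot] <- knots[match(tout[isknot], t), 2]
  pts <- cbind(sx, sy)
  list(pts = pts, is_knot = isknot, knot_index = match(tout, t))
}

#' Rebuild an edited contour and re-reduce it
#'
#' If any point carries the `user-moved` flag, the edited spans are
#' reconstructed by a piecewise cubic interpolation curve through the
#' moved points (anchored at the neighboring unmodified points, or closed
#' periodic when every point moved), densely sampled at 1-pixel steps;
#' the sampled curve is merged with the untouched original points and the
#' reduction algorithm runs on the merged contour at `percent`. The
#' interpolant passes through every user-moved point exactly, and those
#' points survive the reduction.
#'
#' @param contour a [slice_contour()] possibly containing moved points.
#' @param percent target retention for the final reduction.
#' @return the refined [slice_contour()].
#' @export
refine_contour <- function(contour, percent = 20) {
  stopifnot(inherits(contour, "slice_contour"))
  moved <- contour$flags == "user-moved"
  if (!any(moved)) return(simplify_contour(contour, percent))
  pts <- contour$points
  n <- nrow(pts)
  if (all(moved)) {
    s <- sample_cubic_through(pts, step = 1, periodic = TRUE)
    newpts <- s$pts[-nrow(s$pts), , drop = FALSE]  # drop duplicated closure
    flags <- ifelse(s$is_knot[-length(s$is_knot)], "user-moved", "synthetic")
  } else {
    # walk the cycle, replacing maximal runs of moved points
    newpts <- NULL; flags <- character(0)
    i <- 1
    # rotate so position 1 is unmoved (an anchor exists)
    rot <- which(!moved)[1]
    ord <- c(rot:n, seq_len(rot - 1))
    pts <- pts[ord, , drop = FALSE]
    moved <- moved[ord]
    oflags <- contour$flags[ord]
    while (i <= n) {
      if (!moved[i]) {
        newpts <- rbind(newpts, pts[i, ]); flags <- c(flags, oflags[i])
        i <- i + 1
      } else {
        j <- i
        while (j <= n && moved[j]) j <- j + 1
        a <- i - 1                      # anchor before (exists, >= 1)
        b <- if (j > n) 1 else j        # anchor after (wraps to start)
        knots <- pts[c(a, i:(j - 1), b), , drop = FALSE]
        s <- sample_cubic_through(knots, step = 1)
        inner <- s$pts[-c(1, nrow(s$pts)), , drop = FALSE]
        ik <- s$is_knot[-c(1, length(s$is_knot))]
        newpts <- rbind(newpts, inner)
        flags <- c(flags, ifelse(ik, "user-moved", "synthetic"))
        i <- j
      }
    }
  }
  refined <- slice_contour(newpts, contour$slice, flags = flags,
                           axis = contour$axis,
                           original_count = contour$original_count,
                           retained_percent = 100)
  simplify_contour(refined, percent)
}

#' Rasterize contours into a label mask
#'
#' Per-slice even-odd polygon fill with pixel-center inclusion.
#'
#' @param contours list of [slice_contour()].
#' @param dim 3-element grid shape.
#' @param spacing,origin grid geometry for the resulting mask.
#' @param label label value to write; `label_table` names it.
#' @param label_table named label table for the output mask.
#' @return a [label_mask()].
#' @export
rasterize_contours <- function(contours, dim, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0), label = 1L,
                               label_table = c(object = 1L)) {
  lab <- array(0L, dim)
  for (cc in contours) {
    stopifnot(inherits(cc, "slice_contour"))
    if (!contour_is_simple(cc$points))
      stop("self-intersecting contour on slice ", cc$slice)
    pts <- cc$points
    rmin <- max(ceiling(min(pts[, 1])), 0)
    rmax <- min(floor(max(pts[, 1])), dim[1] - 1)
    if (rmax < rmin) next
    y <- pts[, 1]; x <- pts[, 2]
    n <- nrow(pts)
    jn <- c(seq_len(n)[-1], 1)
    for (r in rmin:rmax) {
      up <- (y > r) != (y[jn] > r)
      if (!any(up)) next
      xi <- x[up] + (r - y[up]) * (x[jn][up] - x[up]) / (y[jn][up] - y[up])
      xi <- sort(xi)
      for (m in seq_len(length(xi) %/% 2)) {
        c0 <- ceiling(xi[2 * m - 1]); c1 <- ceiling(xi[2 * m]) - 1
        c0 <- max(c0, 0); c1 <- min(c1, dim[2] - 1)
        if (c1 >= c0) lab[r + 1, (c0:c1) + 1, cc$slice] <- as.integer(label)
      }
    }
  }
  label_mask(lab, spacing, origin, label_table = label_table)
}

#' Ingest manually drawn contours from JSON
#'
#' Schema: `{"objects": [{"id": ..., "label": ..., "slices": [{"index": k,
#' "points": [[r, c], ...]}]}]}`. All points are flagged `user-moved`
#' (user-drawn); open or degenerate polylines are rejected.
#'
#' @param path JSON file path, or an already-parsed list.
#' @return named list of contour lists, one entry per object id, each with
#'   the object's `label` attached as attribute `label`.
#' @export
manual_contour_ingest <- function(path) {
  doc <- if (is.character(path)) jsonlite::read_json(path) else path
  if (is.null(doc$objects)) stop("contour JSON lacks an 'objects' array")
  out <- list()
  for (ob in doc$objects) {
    contours <- list()
    for (sl in ob$slices) {
      pts <- do.call(rbind, lapply(sl$points, function(p) as.numeric(unlist(p))))
      if (is.null(pts) || nrow(pts) < 3)
        stop("polyline with fewer than 3 points on slice ", sl$index)
      if (nrow(pts) >= 2 && all(abs(pts[1, ] - pts[nrow(pts), ]) < 1e-9))
        pts <- pts[-nrow(pts), , drop = FALSE]
      if (nrow(pts) < 3 || abs(shoelace(pts)) < 1e-9)
        stop("degenerate polyline on slice ", sl$index)
      contours[[length(contours) + 1]] <-
        slice_contour(pts, slice = sl$index,
                      flags = rep("user-moved", nrow(pts)))
    }
    attr(contours, "label") <- if (is.null(ob$label)) "object" else ob$label
    out[[as.character(ob$id)]] <- contours
  }
  out
}

#' Apply a contour edit
#'
#' Operations: `move_point` (payload: `point` 1-based index, `to` new
#' (row, col)), `set_retained_percent` (payload: `percent`, triggers
#' [refine_contour()]), `replace_contour` (payload: `points`), and
#' `delete` (returns `NULL`).
#'
#' @param contour a [slice_contour()].
#' @param edit list with `op` and payload fields.
#' @return the edited contour (or `NULL` for `delete`).
#' @export
apply_contour_edit <- function(contour, edit) {
  op <- edit$op
  if (op == "delete") return(NULL)
  stopifnot(inherits(contour, "slice_contour"))
  if (op == "move_point") {
    i <- edit$point
    if (is.null(i) || i < 1 || i > nrow(contour$points))
      stop("move_point: point index does not exist")
    contour$points[i, ] <- as.numeric(unlist(edit$to))
    contour$flags[i] <- "user-moved"
    return(contour)
  }
  if (op == "set_retained_percent")
    return(refine_contour(contour, edit$percent))
  if (op == "replace_contour") {
    pts <- do.call(rbind, lapply(edit$points, function(p) as.numeric(unlist(p))))
    return(slice_contour(pts, contour$slice,
                         flags = rep("user-moved", nrow(pts)),
                         axis = contour$axis))
  }
  stop("unknown contour edit operation: ", op)
}

#' Write contours to the interchange JSON schema
#'
#' @param objects named list: object id -> list of [slice_contour()] (with
#'   optional `label` attribute), as produced by [manual_contour_ingest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contours_json <- function(objects, path) {
  doc <- list(objects = lapply(names(objects), function(id) {
    contours <- objects[[id]]
    list(id = id,
         label = attr(contours, "label") %||% "object",
         slices = lapply(contours, function(cc)
           list(index = cc$slice,
                points = apply(cc$points, 1, as.numeric, simplify = FALSE),
                flags = cc$flags,
                retained_percent = cc$retained_percent)))
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
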