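# Treatment-report rendering (HTML with machine-checkable section markers,
# optional PDF export) and field overlays on anatomy slices.

# boundary of a thresholded region on a 2D slice (4-neighbor interior test)
threshold_isocontour <- function(Esl, level) {
  m <- Esl >= level
  if (!any(m)) return(m & FALSE)
  d <- dim(m)
  inner <- m
  inner[] <- FALSE
  if (all(d >= 3)) {
    core <- m[2:(d[1] - 1), 2:(d[2] - 1)] &
      m[1:(d[1] - 2), 2:(d[2] - 1)] & m[3:d[1], 2:(d[2] - 1)] &
      m[2:(d[1] - 1), 1:(d[2] - 2)] & m[2:(d[1] - 1), 3:d[2]]
    inner[2:(d[1] - 1), 2:(d[2] - 1)] <- core
  }
  m & !inner
}

#' Overlay a field map on an anatomy slice
#'
#' Grayscale anatomy with a semi-transparent heat colormap of the field
#' (fully transparent at zero field) and iso-contour lines at the
#' reversible (cyan) and irreversible (red) thresholds. Output is an RGB
#' array of the slice dimensions times `scale`.
#'
#' @param vol [image_volume()] supplying the anatomy.
#' @param E field grid, V/cm, same shape.
#' @param slice 1-based slice index.
#' @param thresholds `c(e_rev, e_irr)` V/cm.
#' @param scale integer up-scaling factor.
#' @param max_alpha opacity of the field colormap at/above `e_irr`.
#' @return numeric array `(nx*scale, ny*scale, 3)` with values in `[0, 1]`.
#' @export
overlay_field_slice <- function(vol, E, slice, thresholds, scale = 1L,
                                max_alpha = 0.5) {
  stopifnot(inherits(vol, "ept_volume"))
  d <- dim(vol$voxels)
  if (slice < 1 || slice > d[3]) stop("slice index out of range")
  stopifnot(identical(dim(E), d))
  base <- vol$voxels[, , slice]
  rng <- range(base)
  gray <- if (diff(rng) > 0) (base - rng[1]) / diff(rng) else base * 0
  Esl <- E[, , slice]
  alpha <- pmin(Esl / thresholds[2], 1) * max_alpha
  # heat map: red ramps in first, then green (yellow at the top)
  fr <- pmin(Esl / thresholds[1], 1)
  fg <- pmin(pmax(Esl - thresholds[1], 0) / max(thresholds[2] - thresholds[1],
                                                1e-9), 1)
  out <- array(0, c(d[1], d[2], 3))
  out[, , 1] <- gray * (1 - alpha) + fr * alpha
  out[, , 2] <- gray * (1 - alpha) + fg * alpha
  out[, , 3] <- gray * (1 - alpha)
  rev_line <- threshold_isocontour(Esl, thresholds[1])
  irr_line <- threshold_isocontour(Esl, thresholds[2])
  for (ch in 1:3) {
    pl <- out[, , ch]
    pl[rev_line] <- c(0, 1, 1)[ch]
    pl[irr_line] <- c(1, 0, 0)[ch]
    out[, , ch] <- pl
  }
  if (scale > 1L) {
    up <- array(0, c(d[1] * scale, d[2] * scale, 3))
    for (ch in 1:3)
      up[, , ch] <- out[, , ch][rep(seq_len(d[1]), each = scale),
                                rep(seq_len(d[2]), each = scale)]
    out <- up
  }
  out
}

#' Treatment plan bundle
#'
#' Everything the report needs: case id, the volume, tissue mask, electrode
#' array, optimized [optimize_pair_voltages()] plan (with its field
#' solution), per-tissue coverage curves, and the pulse protocol.
#'
#' @param case_id character case identifier.
#' @param volume,tissue,array,plan,protocol pipeline artifacts.
#' @param curves named list of `coverage_curve` per tissue; `NULL` =
#'   computed here for every tissue in the label table.
#' @return object of class `treatment_plan_bundle`.
#' @export
treatment_plan_bundle <- function(case_id, volume, tissue, array, plan,
                                  protocol, curves = NULL) {
  stopifnot(inherits(volume, "ept_volume"), inherits(tissue, "ept_mask"),
            inherits(array, "electrode_array"), inherits(plan, "voltage_plan"),
            inherits(protocol, "pulse_protocol"))
  check_same_grid(volume, tissue)
  if (is.null(curves)) {
    curves <- lapply(names(tissue$label_table), function(nm) {
      m <- mask_of(tissue, nm)
      if (!any(m)) return(NULL)
      cumulative_coverage_curve(plan$solution$E_max, m)
    })
    names(curves) <- names(tissue$label_table)
    curves <- curves[!vapply(curves, is.null, TRUE)]
  }
  structure(list(case_id = case_id, volume = volume, tissue = tissue,
                 array = array, plan = plan, protocol = protocol,
                 curves = curves),
            class = "treatment_plan_bundle")
}

svg_curve <- function(curve, w = 420, h = 260, pad = 40) {
  xs <- pad + curve$threshold / max(max(curve$threshold), 1e-9) * (w - 2 * pad)
  ys <- h - pad - curve$fraction * (h - 2 * pad)
  pts <- paste(sprintf("%.1f,%.1f", xs, ys), collapse = " ")
  sprintf(paste0(
    '<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">',
    '<rect width="%d" height="%d" fill="white" stroke="black"/>',
    '<polyline points="%s" fill="none" stroke="crimson" stroke-width="2"/>',
    '<text x="%d" y="%d" font-size="11">E threshold (V/cm), 0..%.0f</text>',
    '<text x="12" y="%d" font-size="11" transform="rotate(-90 12 %d)">covered fraction</text>',
    "</svg>"),
    w, h, w, h, pts, pad, h - 8, max(curve$threshold), h / 2, h / 2)
}

svg_views <- function(bundle, w = 220) {
  # three orthogonal silhouettes of the tissue mask with projected tips
  m <- bundle$tissue$labels > 0L
  sp <- bundle$tissue$spacing
  tips <- bundle$array$tips
  panels <- character(3)
  axes <- list(c(1, 2), c(1, 3), c(2, 3))
  for (a in 1:3) {
    proj <- apply(m, axes[[a]], any)
    d <- dim(proj)
    sc <- w / max(d)
    cells <- which(proj, arr.ind = TRUE)
    rects <- paste(sprintf(
      '<rect x="%.1f" y="%.1f" width="%.2f" height="%.2f" fill="#9ab"/>',
      (cells[, 1] - 1) * sc, (cells[, 2] - 1) * sc, sc, sc), collapse = "")
    tp <- tips[, axes[[a]], drop = FALSE]
    tipc <- paste(sprintf(
      '<circle cx="%.1f" cy="%.1f" r="3" fill="red"/>',
      tp[, 1] / sp[axes[[a]][1]] * sc, tp[, 2] / sp[axes[[a]][2]] * sc),
      collapse = "")
    panels[a] <- sprintf(
      '<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg"><rect width="%d" height="%d" fill="white" stroke="black"/>%s%s</svg>',
      w, w, w, w, rects, tipc)
  }
  paste(panels, collapse = "\n")
}

svg_overlay <- function(bundle, slice, max_px = 64) {
  th <- protocol_thresholds(bundle$protocol)
  trg <- th[th$tissue == bundle$plan$target, ]
  img <- overlay_field_slice(bundle$volume, bundle$plan$solution$E_max, slice,
                             c(trg$e_rev, trg$e_irr))
  d <- dim(img)
  step <- max(1L, ceiling(max(d[1:2]) / max_px))
  ri <- seq(1, d[1], by = step); ci <- seq(1, d[2], by = step)
  px <- 256 / max(length(ri), length(ci))
  cells <- expand.grid(i = seq_along(ri), j = seq_along(ci))
  cols <- grDevices::rgb(img[cbind(ri[cells$i], ci[cells$j], 1)],
                         img[cbind(ri[cells$i], ci[cells$j], 2)],
                         img[cbind(ri[cells$i], ci[cells$j], 3)])
  rects <- paste(sprintf(
    '<rect x="%.1f" y="%.1f" width="%.2f" height="%.2f" fill="%s"/>',
    (cells$j - 1) * px, (cells$i - 1) * px, px, px, cols), collapse = "")
  sprintf('<svg width="256" height="256" xmlns="http://www.w3.org/2000/svg">%s</svg>',
          rects)
}

#' Render the treatment report
#'
#' Writes an HTML document (optionally also a PDF) containing the four
#' report panels: (A) orthogonal model views with electrode positions,
#' (B) the optimal-voltage table per electrode pair, (C) cumulative
#' coverage curves for the tumor, (D) field overlays on the original
#' images — plus the reversibly/irreversibly treated volumes per tissue.
#' All numbers are taken verbatim from the bundle (no recomputation), and
#' the HTML is byte-deterministic for identical bundles (no timestamps).
#'
#' @param bundle a [treatment_plan_bundle()].
#' @param path output path (`.html`).
#' @param formats subset of `c("html", "pdf")`.
#' @return `path`, invisibly.
#' @export
render_treatment_report <- function(bundle, path, formats = "html") {
  stopifnot(inherits(bundle, "treatment_plan_bundle"))
  plan <- bundle$plan
  th <- protocol_thresholds(bundle$protocol)
  vrow <- sprintf("<tr><td>%d</td><td>%d-%d</td><td>%g</td></tr>",
                  seq_len(nrow(plan$pairs)), plan$pairs[, 1], plan$pairs[, 2],
                  plan$voltages)
  tiprows <- sprintf("<tr><td>%d</td><td>%.1f</td><td>%.1f</td><td>%.1f</td></tr>",
                     seq_len(nrow(bundle$array$tips)), bundle$array$tips[, 1],
                     bundle$array$tips[, 2], bundle$array$tips[, 3])
  volrows <- sprintf("<tr><td>%s</td><td>%.0f</td></tr>",
                     names(plan$irreversible_volumes_mm3),
                     plan$irreversible_volumes_mm3)
  curves_html <- vapply(names(bundle$curves), function(nm)
    sprintf("<h3>%s</h3>\n%s", nm, svg_curve(bundle$curves[[nm]])), "")
  mid <- which.max(apply(mask_of(bundle$tissue, plan$target), 3, sum))
  html <- paste(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    sprintf("<title>Treatment report %s</title></head><body>", bundle$case_id),
    sprintf("<h1>Treatment report: case %s</h1>", bundle$case_id),
    sprintf("<p>Protocol: %s, %d pulses of %g &micro;s at %g Hz.</p>",
            bundle$protocol$mode, bundle$protocol$pulses,
            bundle$protocol$duration_us, bundle$protocol$frequency_hz),
    sprintf("<p>Target %s coverage at %g V/cm: <b>%.1f%%</b> (%s)</p>",
            plan$target, plan$e_rev, 100 * plan$coverage,
            if (plan$feasible) "feasible" else "infeasible"),
    "<!-- SECTION:model-views -->",
    "<h2>A. Model and electrode positions</h2>",
    sprintf("<p>Electrode %s, %d needles, trajectory (%.1f, %.1f, %.1f) &rarr; (%.1f, %.1f, %.1f) mm, active length %g mm.</p>",
            bundle$array$spec$id, nrow(bundle$array$tips),
            bundle$array$entry[1], bundle$array$entry[2],
            bundle$array$entry[3], bundle$array$target[1],
            bundle$array$target[2], bundle$array$target[3],
            bundle$array$active_length),
    svg_views(bundle),
    "<table border='1'><tr><th>needle</th><th>tip x</th><th>tip y</th><th>tip z</th></tr>",
    paste(tiprows, collapse = "\n"), "</table>",
    "<!-- SECTION:voltage-table -->",
    "<h2>B. Optimal voltages per electrode pair</h2>",
    "<table border='1'><tr><th>#</th><th>pair</th><th>voltage (V)</th></tr>",
    paste(vrow, collapse = "\n"), "</table>",
    "<!-- SECTION:coverage-curves -->",
    "<h2>C. Cumulative coverage curves</h2>",
    paste(curves_html, collapse = "\n"),
    "<!-- SECTION:field-overlays -->",
    "<h2>D. Electric field distribution over the original images</h2>",
    sprintf("<p>Central target slice %d; cyan iso-line = reversible threshold, red = irreversible.</p>", mid),
    svg_overlay(bundle, mid),
    "<!-- SECTION:treated-volumes -->",
    "<h2>Irreversibly treated volumes per tissue</h2>",
    "<table border='1'><tr><th>tissue</th><th>volume &ge; E_irr (mm&sup3;)</th></tr>",
    paste(volrows, collapse = "\n"), "</table>",
    "</body></html>", sep = "\n")
  writeLines(html, path)
  if ("pdf" %in% formats) {
    pdf_path <- sub("\\.html?$", ".pdf", path)
    if (pdf_path == path) pdf_path <- paste0(path, ".pdf")
    grDevices::pdf(pdf_path, width = 8, height = 10)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(2, 2), mar = c(4, 4, 3, 1))
    m <- bundle$tissue$labels > 0L
    graphics::image(apply(m, c(1, 2), any), col = c("white", "#99aabb"),
                    main = "A. Model (axial projection)", axes = FALSE)
    graphics::plot.new()
    graphics::title(main = "B. Voltages per pair")
    graphics::text(0.1, seq(0.9, 0.1, length.out = nrow(plan$pairs)),
                   sprintf("pair %d-%d: %g V", plan$pairs[, 1],
                           plan$pairs[, 2], plan$voltages), adj = 0)
    cc <- bundle$curves[[plan$target]]
    if (!is.null(cc))
      graphics::plot(cc$threshold, cc$fraction, type = "l", col = "red3",
                     xlab = "E (V/cm)", ylab = "covered fraction",
                     main = "C. Cumulative coverage", ylim = c(0, 1))
    graphics::image(bundle$plan$solution$E_max[, , mid],
                    main = sprintf("D. |E| on slice %d", mid), axes = FALSE)
  }
  invisible(path)
}
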