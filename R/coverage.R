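# Coverage statistics on cumulative field maps, dose-volume-histogram-style
# coverage curves, and per-pair voltage optimization.

#' Fraction of a mask covered at or above a field threshold
#'
#' @param E field magnitude grid, V/cm.
#' @param mask logical array (or [label_mask()], any nonzero label).
#' @param threshold V/cm; comparison is inclusive (`>=`).
#' @return fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(E, mask, threshold) {
  if (inherits(mask, "ept_mask")) mask <- mask$labels > 0L
  stopifnot(identical(dim(E), dim(mask)))
  n <- sum(mask)
  if (n == 0) stop("empty mask")
  sum(E[mask] >= threshold) / n
}

#' Cumulative coverage curve
#'
#' Volume fraction of the mask with `E >= t` for thresholds linearly spaced
#' from 0 to the maximum field inside the mask. Nonincreasing by
#' construction; the fraction at threshold 0 is 1.
#'
#' @param E field grid, V/cm.
#' @param mask logical array or [label_mask()].
#' @param n number of thresholds.
#' @return object of class `coverage_curve`: data frame with `threshold`
#'   (V/cm) and `fraction`.
#' @export
cumulative_coverage_curve <- function(E, mask, n = 50) {
  if (inherits(mask, "ept_mask")) mask <- mask$labels > 0L
  stopifnot(identical(dim(E), dim(mask)))
  if (!sum(mask)) stop("empty mask")
  thr <- seq(0, max(E[mask]), length.out = n)
  frac <- vapply(thr, function(t) coverage_fraction(E, mask, t), 0)
  structure(data.frame(threshold = thr, fraction = frac),
            class = c("coverage_curve", "data.frame"))
}

# solve the sequence and return target coverage at e_rev + the solution
eval_voltages <- function(voltages, tissue, elec, array, target_mask, e_rev,
                          properties, tol, max_iter) {
  fs <- solve_sequence(tissue, elec, array, voltages, properties,
                       tol = tol, max_iter = max_iter)
  list(coverage = coverage_fraction(fs$E_max, target_mask, e_rev),
       solution = fs)
}

#' Optimize per-pair voltages for target coverage
#'
#' Finds minimal voltages (to within `delta_u`) such that the cumulative
#' field covers the required fraction of the target at the reversible
#' threshold, subject to the generator/spec voltage cap: first bisection on
#' a common voltage applied to all pairs, then a per-pair descent that
#' lowers each pair individually while coverage holds. Healthy-tissue
#' volumes at or above the irreversible threshold are reported (not
#' constrained). Deterministic.
#'
#' @param tissue tissue [label_mask()]; must contain `target` in its table.
#' @param elec electrode label grid.
#' @param array `electrode_array`.
#' @param properties tissue table.
#' @param protocol a [pulse_protocol()]; resolves the thresholds.
#' @param target target tissue name (default "tumor").
#' @param required_coverage required fraction at `e_rev` (default 1.0).
#' @param delta_u voltage search tolerance, V.
#' @param u_min,u_max search bounds; `u_max` defaults to the electrode
#'   spec's maximum voltage.
#' @param tol,max_iter nonlinear solver controls.
#' @return object of class `voltage_plan`: pair sequence, voltage per pair,
#'   achieved coverage, per-tissue irreversibly treated volumes (mm^3),
#'   feasibility flag, and the final `field_solution`.
#' @export
optimize_pair_voltages <- function(tissue, elec, array,
                                   properties = tissue_properties(),
                                   protocol = pulse_protocol("ECT"),
                                   target = "tumor",
                                   required_coverage = 1.0, delta_u = 10,
                                   u_min = 100, u_max = NULL,
                                   tol = 1e-3, max_iter = 20) {
  stopifnot(inherits(tissue, "ept_mask"))
  if (!target %in% names(tissue$label_table))
    stop("target label '", target, "' not present")
  th <- protocol_thresholds(protocol, properties)
  e_rev <- th$e_rev[th$tissue == target]
  target_mask <- mask_of(tissue, target)
  if (is.null(u_max)) u_max <- array$spec$max_voltage
  npair <- nrow(array$pairs)
  ev <- function(v) eval_voltages(v, tissue, elec, array, target_mask, e_rev,
                                  properties, tol, max_iter)

  hi <- ev(rep(u_max, npair))
  if (hi$coverage < required_coverage) {
    plan <- voltage_plan(array, rep(u_max, npair), hi, tissue, th,
                         feasible = FALSE, e_rev = e_rev, target = target)
    return(plan)
  }
  lo_res <- ev(rep(u_min, npair))
  if (lo_res$coverage >= required_coverage) {
    lo <- u_min; best <- lo_res
  } else {
    # bisect the common scale
    lo_v <- u_min; hi_v <- u_max; best <- hi
    while (hi_v - lo_v > delta_u) {
      mid <- (lo_v + hi_v) / 2
      r <- ev(rep(mid, npair))
      if (r$coverage >= required_coverage) { hi_v <- mid; best <- r }
      else lo_v <- mid
    }
    lo <- hi_v
  }
  voltages <- rep(lo, npair)
  # per-pair descent: bisect each pair's voltage down, keeping coverage
  if (npair > 1) {
    for (p in seq_len(npair)) {
      lo_v <- u_min; hi_v <- voltages[p]
      vtry <- voltages
      vtry[p] <- u_min
      r <- ev(vtry)
      if (r$coverage >= required_coverage) { voltages[p] <- u_min; best <- r }
      else {
        while (hi_v - lo_v > delta_u) {
          mid <- (lo_v + hi_v) / 2
          vtry[p] <- mid
          r <- ev(vtry)
          if (r$coverage >= required_coverage) { hi_v <- mid; best <- r }
          else lo_v <- mid
        }
        voltages[p] <- hi_v
      }
      if (!identical(voltages[p], best$solution$voltages[p])) {
        best <- ev(voltages)
      }
    }
  }
  voltage_plan(array, voltages, best, tissue, th, feasible = TRUE,
               e_rev = e_rev, target = target)
}

voltage_plan <- function(array, voltages, evalres, tissue, thresholds,
                         feasible, e_rev, target) {
  vox_mm3 <- prod(tissue$spacing)
  irr <- lapply(names(tissue$label_table), function(nm) {
    m <- mask_of(tissue, nm)
    e_irr <- thresholds$e_irr[thresholds$tissue == nm]
    if (!any(m)) return(0)
    sum(evalres$solution$E_max[m] >= e_irr) * vox_mm3
  })
  names(irr) <- names(tissue$label_table)
  structure(list(pairs = array$pairs, voltages = voltages,
                 coverage = evalres$coverage, e_rev = e_rev, target = target,
                 irreversible_volumes_mm3 = unlist(irr),
                 feasible = feasible, solution = evalres$solution),
            class = "voltage_plan")
}

#' @export
print.voltage_plan <- function(x, ...) {
  cat(sprintf("<voltage_plan %s: %s coverage %.3f at %g V/cm>\n",
              if (x$feasible) "feasible" else "INFEASIBLE",
              x$target, x$coverage, x$e_rev))
  for (p in seq_len(nrow(x$pairs)))
    cat(sprintf("  pair %d-%d: %g V\n", x$pairs[p, 1], x$pairs[p, 2],
                x$voltages[p]))
  invisible(x)
}

#' Escalate needle count until the plan is feasible
#'
#' For variable-geometry electrodes: starts from 2 needles and, while
#' [optimize_pair_voltages()] is infeasible at the voltage cap, adds one
#' needle on the symmetric placement row (positions nearest the target
#' first, which the symmetric row realizes by construction) and
#' re-optimizes; stops at feasibility or `max_needles`.
#'
#' @param tissue,properties,protocol,target,required_coverage,delta_u,u_min,u_max,tol,max_iter
#'   as in [optimize_pair_voltages()].
#' @param spec variable-geometry `electrode_spec`.
#' @param entry,target_point trajectory, mm.
#' @param grid_dim,spacing,origin solving grid geometry.
#' @param needle_spacing inter-needle spacing, mm.
#' @param max_needles escalation cap.
#' @return list: `array` (the final `electrode_array`) and `plan`
#'   (`voltage_plan`, `feasible` flag indicates success).
#' @export
plan_needle_count <- function(tissue, spec, entry, target_point,
                              grid_dim, spacing, origin = c(0, 0, 0),
                              needle_spacing = 10, max_needles = 6,
                              active_length = NULL,
                              properties = tissue_properties(),
                              protocol = pulse_protocol("ECT"),
                              target = "tumor", required_coverage = 1.0,
                              delta_u = 10, u_min = 100, u_max = NULL,
                              tol = 1e-3, max_iter = 20) {
  if (spec$style != "variable")
    stop("needle-count planning applies to variable-geometry specs")
  n <- 2L
  repeat {
    array <- place_parallel_array(spec, entry, target_point, n = n,
                                  spacing = needle_spacing,
                                  active_length = active_length)
    elec <- rasterize_electrodes(array, grid_dim, spacing, origin)
    plan <- optimize_pair_voltages(tissue, elec, array, properties, protocol,
                                   target, required_coverage, delta_u,
                                   u_min, u_max, tol, max_iter)
    if (plan$feasible || n >= max_needles)
      return(list(array = array, plan = plan, needles = n))
    n <- n + 1L
  }
}
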