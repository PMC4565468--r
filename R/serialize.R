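# JSON/CSV interchange for arrays, plans and coverage curves.

#' Serialize / deserialize an electrode array as JSON
#'
#' The spec is stored by id plus the placement inputs, so a round-trip
#' reconstructs the array through [place_parallel_array()].
#'
#' @param array an `electrode_array`.
#' @param path JSON path.
#' @param catalog_path catalog used to resolve the spec id on read.
#' @return `path` invisibly / the reconstructed `electrode_array`.
#' @export
write_array_json <- function(array, path) {
  stopifnot(inherits(array, "electrode_array"))
  n <- nrow(array$tips)
  doc <- list(spec_id = array$spec$id,
              entry = array$entry,
              target = array$target,
              n = n,
              spacing = if (n >= 2 && array$spec$style == "variable")
                sqrt(sum((array$tips[2, ] - array$tips[1, ])^2)) else NULL,
              active_length = array$active_length,
              direction = array$direction,
              tips = apply(array$tips, 1, as.numeric, simplify = FALSE),
              pairs = apply(array$pairs, 1, as.integer, simplify = FALSE))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_array_json
#' @export
read_array_json <- function(path, catalog_path = system.file(
                              "extdata", "electrode_catalog.json",
                              package = "eptplan")) {
  doc <- jsonlite::read_json(path)
  spec <- electrode_spec_by_id(doc$spec_id, catalog_path)
  arr <- place_parallel_array(spec, as.numeric(unlist(doc$entry)),
                              as.numeric(unlist(doc$target)),
                              n = doc$n,
                              spacing = if (is.null(doc$spacing)) 10 else
                                doc$spacing,
                              active_length = doc$active_length)
  arr
}

#' Write a voltage plan as JSON
#'
#' Pairs, voltages, achieved coverage and irreversibly treated volumes —
#' the machine-readable companion of the report's voltage table.
#'
#' @param plan a `voltage_plan`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "voltage_plan"))
  doc <- list(target = plan$target, e_rev = plan$e_rev,
              feasible = plan$feasible, coverage = plan$coverage,
              pairs = apply(plan$pairs, 1, as.integer, simplify = FALSE),
              voltages = plan$voltages,
              irreversible_volumes_mm3 =
                as.list(plan$irreversible_volumes_mm3))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a coverage curve as CSV
#'
#' @param curve a `coverage_curve`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
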