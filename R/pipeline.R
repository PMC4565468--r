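# Staged pipeline runner with a content-addressed stage cache, mirroring the
# clinical workflow: import -> segment -> validate -> electrodes -> solve ->
# plan -> report.

# md5 of the serialized object (tools::md5sum is file-based)
content_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(obj, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

stage_cache_get <- function(cache_dir, key) {
  f <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(f)) readRDS(f) else NULL
}

stage_cache_put <- function(cache_dir, key, value) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(value, file.path(cache_dir, paste0(key, ".rds")))
  value
}

PIPELINE_STAGE_DEPS <- list(
  phantom = character(0),
  import = character(0),
  segment = "volume",
  validate = c("volume", "tissue"),
  electrodes = "volume",
  plan = c("tissue", "array"),
  report = c("plan", "array", "tissue", "volume"))

#' Run a staged planning procedure
#'
#' Executes the configured stage sequence in order, validating that each
#' stage's inputs were produced by an earlier stage (a missing dependency
#' is an error naming both stages), logging per-stage wall times, and
#' caching stage outputs by a content hash of the stage parameters and
#' inputs so re-runs skip completed work.
#'
#' Stage names and their parameter lists:
#' \describe{
#'   \item{phantom}{`spec` = a [phantom_spec()]; yields volume + truth.}
#'   \item{import}{`path` = DICOM series directory.}
#'   \item{segment}{`targets` = subset of liver-ct, liver-mri, vessels,
#'     bone; `seed` for liver-mri. Merges results into one tissue mask.}
#'   \item{validate}{`edits_json` = contour-edit file applied to the tissue
#'     mask at `label`, or omitted for a no-op validation pass.}
#'   \item{electrodes}{`electrode_id`, `entry`, `target_point`, optional
#'     `n`, `needle_spacing`, `active_length`.}
#'   \item{plan}{`protocol_mode`, optional `target`, `required_coverage`,
#'     `delta_u`, `u_max`.}
#'   \item{report}{`path` for the HTML report.}
#' }
#'
#' @param config list with `case_id`, `outdir` and `stages` (list of
#'   `list(name = ..., params)`), or a path to a JSON file with the same
#'   shape.
#' @return a [treatment_plan_bundle()] (invisibly) when the sequence
#'   includes `report`; otherwise the final state list.
#' @export
run_procedure <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = FALSE)
  stages <- config$stages
  outdir <- config$outdir %||% tempfile("eptplan_case_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(outdir, "cache")
  state <- list(case_id = config$case_id %||% "case")
  produced_by <- list()
  bundle <- NULL

  for (si in seq_along(stages)) {
    st <- stages[[si]]
    nm <- st$name
    if (is.null(nm) || !nm %in% names(PIPELINE_STAGE_DEPS))
      stop("unknown stage: ", if (is.null(nm)) "<unnamed>" else nm)
    for (dep in PIPELINE_STAGE_DEPS[[nm]])
      if (is.null(state[[dep]]))
        stop("stage '", nm, "' requires '", dep,
             "' which no earlier stage produced (add e.g. '",
             c(volume = "import", tissue = "segment", array = "electrodes",
               plan = "plan")[dep], "' before it)")
    t0 <- Sys.time()
    key <- content_hash(list(nm, st, lapply(PIPELINE_STAGE_DEPS[[nm]],
                                            function(dep) state[[dep]])))
    cached <- stage_cache_get(cache_dir, key)
    if (!is.null(cached)) {
      state[names(cached)] <- cached
      message(sprintf("[%s] cached (%.2fs)", nm,
                      as.numeric(Sys.time() - t0, units = "secs")))
    } else {
      res <- run_stage(nm, st, state)
      state[names(res)] <- res
      stage_cache_put(cache_dir, key, res)
      message(sprintf("[%s] done in %.2fs", nm,
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
    for (out in names(state)) produced_by[[out]] <- nm
  }
  if (!is.null(state$bundle)) invisible(state$bundle) else invisible(state)
}

run_stage <- function(nm, st, state) {
  p <- st
  num <- function(x) as.numeric(unlist(x))
  switch(nm,
    phantom = {
      spec <- if (inherits(p$spec, "phantom_spec")) p$spec else
        do.call(phantom_spec, lapply(p$spec, function(x)
          if (is.list(x)) num(x) else x))
      ph <- generate_abdomen_phantom(spec)
      list(volume = ph$volume, tissue = ph$truth, phantom_spec = spec)
    },
    import = list(volume = read_dicom_series(p$path)),
    segment = {
      vol <- state$volume
      targets <- unlist(p$targets) %||% "liver-ct"
      labs <- array(0L, dim(vol$voxels))
      tab <- integer(0)
      liver <- NULL
      for (tg in targets) {
        m <- switch(tg,
          `liver-ct` = segment_liver_ct(vol),
          `liver-mri` = segment_liver_mri(vol, num(p$seed)),
          bone = segment_bone_ct(vol),
          vessels = {
            if (is.null(liver)) stop("segment vessels after a liver target")
            segment_vessels(vol, liver)
          },
          brain = segment_canine_brain(vol),
          stop("unknown segmentation target: ", tg))
        if (tg %in% c("liver-ct", "liver-mri")) liver <- m
        for (lnm in names(m$label_table)) {
          labs[m$labels == m$label_table[[lnm]]] <- m$label_table[[lnm]]
          tab[lnm] <- m$label_table[[lnm]]
        }
      }
      list(tissue = label_mask(labs, vol$spacing, vol$origin,
                               label_table = tab))
    },
    validate = {
      if (is.null(p$edits_json)) return(list(validated = TRUE))
      objs <- manual_contour_ingest(p$edits_json)
      tissue <- state$tissue
      labs <- tissue$labels
      tab <- tissue$label_table
      for (id in names(objs)) {
        contours <- objs[[id]]
        lbl_name <- attr(contours, "label")
        lbl <- tab[[lbl_name]] %||% (max(c(0L, tab)) + 1L)
        tab[lbl_name] <- lbl
        m <- rasterize_contours(contours, dim(labs), tissue$spacing,
                                tissue$origin, label = lbl,
                                label_table = stats::setNames(lbl, lbl_name))
        labs[labs == lbl] <- 0L
        labs[m$labels > 0L] <- lbl
      }
      list(tissue = label_mask(labs, tissue$spacing, tissue$origin,
                               label_table = tab),
           validated = TRUE)
    },
    electrodes = {
      spec <- electrode_spec_by_id(p$electrode_id %||% "linear-pair")
      array <- place_parallel_array(spec, num(p$entry), num(p$target_point),
                                    n = p$n %||% 2,
                                    spacing = p$needle_spacing %||% 10,
                                    active_length = p$active_length)
      vol <- state$volume
      elec <- rasterize_electrodes(array, dim(vol$voxels), vol$spacing,
                                   vol$origin)
      list(array = array, elec = elec)
    },
    plan = {
      protocol <- pulse_protocol(p$protocol_mode %||% "ECT")
      plan <- optimize_pair_voltages(
        state$tissue, state$elec, state$array,
        protocol = protocol, target = p$target %||% "tumor",
        required_coverage = p$required_coverage %||% 1.0,
        delta_u = p$delta_u %||% 10, u_max = p$u_max)
      list(plan = plan, protocol = protocol)
    },
    report = {
      bundle <- treatment_plan_bundle(state$case_id, state$volume,
                                      state$tissue, state$array, state$plan,
                                      state$protocol %||% pulse_protocol("ECT"))
      path <- p$path %||% file.path(tempdir(), "report.html")
      render_treatment_report(bundle, path,
                              formats = unlist(p$formats) %||% "html")
      list(bundle = bundle, report_path = path)
    })
}
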