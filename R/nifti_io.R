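# Minimal NIfTI-1 reader/writer (uncompressed .nii, little-endian) and a
# minimal NRRD reader. No NIfTI package exists in the supported dependency
# set, so the subset of the format this package itself produces is handled
# here: single 3D image, axis-aligned sform, float64/int32 data.

NIFTI_DTYPES <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                     `4` = list(what = "integer", size = 2, signed = TRUE),
                     `8` = list(what = "integer", size = 4, signed = TRUE),
                     `16` = list(what = "double", size = 4, signed = TRUE),
                     `64` = list(what = "double", size = 8, signed = TRUE))

nifti_write_raw <- function(arr, spacing, origin, path, datatype) {
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wchr <- function(s, n) {
    r <- charToRaw(s)
    writeBin(c(r, raw(n - length(r))), con)
  }
  wint(348, 4)                       # sizeof_hdr
  writeBin(raw(36), con)             # data_type..dim_info (unused)
  wint(c(3, dim(arr), 1, 1, 1, 1), 2)  # dim[8]
  wflt(c(0, 0, 0)); wint(0, 2)       # intent
  wint(datatype, 2)                  # datatype
  wint(dt$size * 8, 2)               # bitpix
  wint(0, 2)                         # slice_start
  wflt(c(1, spacing, 1, 1, 1, 1))    # pixdim[8]
  wflt(352)                          # vox_offset
  wflt(c(1, 0))                      # scl_slope, scl_inter
  wint(0, 2); writeBin(raw(1), con)  # slice_end, slice_code
  writeBin(as.raw(10L), con)         # xyzt_units: mm + s
  wflt(c(0, 0, 0, 0))                # cal_max..toffset
  wint(c(0, 0), 4)                   # glmax, glmin
  wchr("eptplan", 80); wchr("", 24)  # descrip, aux_file
  wint(c(0, 1), 2)                   # qform_code=0, sform_code=1
  wflt(c(0, 0, 0))                   # quatern b c d
  wflt(origin)                       # qoffset (mirrors sform translation)
  wflt(c(spacing[1], 0, 0, origin[1]))  # srow_x
  wflt(c(0, spacing[2], 0, origin[2]))  # srow_y
  wflt(c(0, 0, spacing[3], origin[3]))  # srow_z
  wchr("", 16); wchr("n+1", 4)       # intent_name, magic
  writeBin(raw(4), con)              # no extensions
  if (dt$what == "integer")
    writeBin(as.integer(arr), con, size = dt$size, endian = "little")
  else
    writeBin(as.numeric(arr), con, size = dt$size, endian = "little")
  invisible(path)
}

nifti_read_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  rint <- function(off, size, n = 1, signed = TRUE)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little", signed = signed)
  rflt <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  if (rint(0, 4) != 348) stop("not a little-endian NIfTI-1 file: ", path)
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1") stop("unsupported NIfTI magic '", magic, "'")
  dims <- rint(40, 2, 8)
  if (dims[1] != 3) stop("only 3D NIfTI volumes supported")
  shape <- dims[2:4]
  datatype <- rint(70, 2)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype)
  pixdim <- rflt(76, 8)
  vox_offset <- rflt(108)
  scl <- rflt(112, 2)
  srow <- matrix(rflt(280, 12), nrow = 3, byrow = TRUE)
  sform_code <- rint(252 + 2, 2)
  origin <- if (sform_code > 0) srow[, 4] else rflt(268, 3)
  seek(con, vox_offset)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = "little",
                  signed = dt$signed)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    vals <- vals * scl[1] + scl[2]
  list(arr = array(vals, shape), spacing = abs(pixdim[2:4]), origin = origin)
}

#' Write / read an image volume as NIfTI-1
#'
#' Volumes are stored as float64 so that write-then-read is an exact
#' identity; geometry goes into an axis-aligned sform.
#'
#' @param vol an [image_volume()].
#' @param path output `.nii` path.
#' @param modality modality to attach on read (NIfTI does not store it).
#' @return `write_volume` returns `path` invisibly; `read_volume` an
#'   [image_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ept_volume"))
  nifti_write_raw(vol$voxels, vol$spacing, vol$origin, path, 64L)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, modality = c("CT", "MRI")) {
  modality <- match.arg(modality)
  r <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) nrrd_read(path)
       else nifti_read_raw(path)
  image_volume(r$arr, r$spacing, r$origin, modality = modality)
}

#' Write / read a label mask (NIfTI + JSON label-table sidecar)
#'
#' Labels are stored as int32; the tissue-name table goes into a
#' `<path>.labels.json` sidecar. Reading validates the geometry round-trip.
#'
#' @param mask an [label_mask()].
#' @param path output `.nii` path (NRRD also accepted by `read_mask`).
#' @return `write_mask` returns `path` invisibly; `read_mask` a mask.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "ept_mask"))
  nifti_write_raw(mask$labels, mask$spacing, mask$origin, path, 8L)
  jsonlite::write_json(as.list(mask$label_table),
                       paste0(path, ".labels.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  r <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) nrrd_read(path)
       else nifti_read_raw(path)
  side <- paste0(path, ".labels.json")
  tab <- if (file.exists(side)) {
    l <- jsonlite::read_json(side)
    stats::setNames(as.integer(unlist(l)), names(l))
  } else {
    u <- sort(unique(as.vector(r$arr))); u <- u[u != 0]
    stats::setNames(as.integer(u), paste0("label", u))
  }
  if (any(r$arr != round(r$arr))) stop("mask file contains non-integer values")
  label_mask(array(as.integer(r$arr), dim(r$arr)), r$spacing, r$origin,
             label_table = tab)
}

# Minimal NRRD reader: raw or ascii encoding, 3D, little-endian.
nrrd_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    l <- readLines(con, n = 1, warn = FALSE)
    if (length(l) == 0 || l == "") break
    lines <- c(lines, l)
  }
  if (!grepl("^NRRD", lines[1])) stop("not an NRRD file: ", path)
  fields <- list()
  for (l in lines[-1]) {
    if (grepl("^#", l)) next
    kv <- strsplit(l, ": ?", fixed = FALSE)[[1]]
    if (length(kv) >= 2) fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ":")
  }
  shape <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  if (length(shape) != 3) stop("only 3D NRRD supported")
  type <- fields$type
  spacing <- c(1, 1, 1)
  if (!is.null(fields$`space directions`)) {
    v <- regmatches(fields$`space directions`,
                    gregexpr("-?[0-9.eE+]+", fields$`space directions`))[[1]]
    m <- matrix(as.numeric(v), nrow = 3)
    spacing <- sqrt(colSums(m^2))
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields$`space origin`)) {
    v <- regmatches(fields$`space origin`,
                    gregexpr("-?[0-9.eE+]+", fields$`space origin`))[[1]]
    origin <- as.numeric(v)
  }
  enc <- tolower(fields$encoding)
  n <- prod(shape)
  vals <- if (enc == "raw") {
    tmap <- list(short = c("integer", 2), int = c("integer", 4),
                 float = c("double", 4), double = c("double", 8),
                 uchar = c("integer", 1))
    tm <- tmap[[type]]
    if (is.null(tm)) stop("unsupported NRRD type ", type)
    readBin(con, tm[1], n = n, size = as.integer(tm[2]), endian = "little",
            signed = !(type == "uchar"))
  } else if (enc %in% c("ascii", "text", "txt")) {
    as.numeric(scan(con, what = numeric(), n = n, quiet = TRUE))
  } else stop("unsupported NRRD encoding ", enc)
  list(arr = array(vals, shape), spacing = spacing, origin = origin)
}
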