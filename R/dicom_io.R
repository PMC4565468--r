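# Minimal single-frame DICOM support: explicit-VR little-endian read/write,
# series assembly, and tag-list anonymization. Covers plain axial CT/MRI
# stacks (the only profile the planning pipeline consumes); multi-frame,
# compressed transfer syntaxes and sequences are out of scope.

DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# Patient-identifying attributes stripped by default; the set is policy, not
# a standard: name, ID, birth date, referring physician, institution, and
# free-text comment fields.
#' @export
default_anonymize_policy <- function() {
  list(
    c(0x0010, 0x0010), # PatientName
    c(0x0010, 0x0020), # PatientID
    c(0x0010, 0x0030), # PatientBirthDate
    c(0x0010, 0x0040), # PatientSex
    c(0x0010, 0x1000), # OtherPatientIDs
    c(0x0010, 0x4000), # PatientComments
    c(0x0008, 0x0090), # ReferringPhysicianName
    c(0x0008, 0x0080), # InstitutionName
    c(0x0008, 0x0081), # InstitutionAddress
    c(0x0008, 0x1070)  # OperatorsName
  )
}

dcm_pad <- function(raw_val, vr) {
  if (length(raw_val) %% 2 == 1)
    raw_val <- c(raw_val, if (vr == "UI") as.raw(0) else charToRaw(" "))
  raw_val
}

dcm_encode_value <- function(value, vr) {
  if (vr %in% c("US", "SS"))
    return(writeBin(as.integer(value), raw(), size = 2, endian = "little"))
  if (vr == "UL")
    return(writeBin(as.integer(value), raw(), size = 4, endian = "little"))
  if (vr == "OW") return(value)  # already raw
  dcm_pad(charToRaw(paste(value, collapse = "\\")), vr)
}

dcm_element_raw <- function(group, elem, vr, value) {
  val <- dcm_encode_value(value, vr)
  head <- writeBin(as.integer(c(group, elem)), raw(), size = 2,
                   endian = "little")
  if (vr %in% DCM_LONG_VRS) {
    c(head, charToRaw(vr), raw(2),
      writeBin(as.integer(length(val)), raw(), size = 4, endian = "little"),
      val)
  } else {
    c(head, charToRaw(vr),
      writeBin(as.integer(length(val)), raw(), size = 2, endian = "little"),
      val)
  }
}

# elements: list of list(group, elem, vr, value); written in tag order.
dcm_write_file <- function(path, elements) {
  ord <- order(vapply(elements, function(e) e$group * 2^16 + e$elem, 0))
  elements <- elements[ord]
  body <- do.call(c, lapply(elements, function(e)
    dcm_element_raw(e$group, e$elem, e$vr, e$value)))
  meta <- list(
    list(group = 0x0002, elem = 0x0002, vr = "UI",
         value = "1.2.840.10008.5.1.4.1.1.2"),
    list(group = 0x0002, elem = 0x0003, vr = "UI",
         value = "1.2.826.0.1.3680043.9999.1"),
    list(group = 0x0002, elem = 0x0010, vr = "UI", value = DCM_EXPLICIT_LE))
  meta_raw <- do.call(c, lapply(meta, function(e)
    dcm_element_raw(e$group, e$elem, e$vr, e$value)))
  grouplen <- dcm_element_raw(0x0002, 0x0000, "UL", length(meta_raw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(grouplen, meta_raw, body), con)
  invisible(path)
}

dcm_parse_file <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 256 || rawToChar(raw_all[129:132]) != "DICM")
    stop("not a DICOM (part-10) file: ", path)
  pos <- 133L
  n <- length(raw_all)
  u16 <- function(p) readBin(raw_all[p:(p + 1)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(p) readBin(raw_all[p:(p + 3)], "integer", size = 4,
                             endian = "little")
  elements <- list()
  while (pos + 7 <= n) {
    group <- u16(pos); elem <- u16(pos + 2)
    vr <- rawToChar(raw_all[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or unsupported transfer syntax in ", path)
    if (vr %in% DCM_LONG_VRS) {
      len <- u32(pos + 8); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6); vstart <- pos + 8L
    }
    if (len < 0 || vstart + len - 1 > n) stop("corrupt DICOM element in ", path)
    val <- if (len > 0) raw_all[vstart:(vstart + len - 1)] else raw()
    elements[[length(elements) + 1]] <-
      list(group = group, elem = elem, vr = vr, raw = val)
    pos <- vstart + len
  }
  ts <- dcm_get_str(elements, 0x0002, 0x0010)
  if (!is.null(ts) && ts != DCM_EXPLICIT_LE)
    stop("unsupported transfer syntax ", ts)
  elements
}

dcm_find <- function(elements, group, elem) {
  for (i in seq_along(elements))
    if (elements[[i]]$group == group && elements[[i]]$elem == elem) return(i)
  NULL
}

# raw -> string with trailing NUL/space padding stripped
dcm_raw_to_str <- function(r) {
  while (length(r) && (r[length(r)] == as.raw(0) || r[length(r)] == as.raw(32)))
    r <- r[-length(r)]
  rawToChar(r)
}

dcm_get_str <- function(elements, group, elem) {
  i <- dcm_find(elements, group, elem)
  if (is.null(i)) return(NULL)
  dcm_raw_to_str(elements[[i]]$raw)
}

dcm_get_num <- function(elements, group, elem) {
  i <- dcm_find(elements, group, elem)
  if (is.null(i)) return(NULL)
  e <- elements[[i]]
  if (e$vr %in% c("US", "SS"))
    return(readBin(e$raw, "integer", n = length(e$raw) / 2, size = 2,
                   endian = "little", signed = e$vr == "SS"))
  if (e$vr == "UL")
    return(readBin(e$raw, "integer", n = length(e$raw) / 4, size = 4,
                   endian = "little"))
  as.numeric(strsplit(dcm_raw_to_str(e$raw), "\\", fixed = TRUE)[[1]])
}

#' Write an image volume as a single-series DICOM stack
#'
#' One explicit-VR little-endian file per axial slice; pixel values are
#' rounded to int16 (phantom volumes are integer-valued, so round-trips are
#' exact).
#'
#' @param vol an [image_volume()].
#' @param dir output directory (created if needed).
#' @param patient_name,patient_id identifying attributes (targets for
#'   [anonymize_dicom()]).
#' @param series_uid series instance UID; one series per call.
#' @return invisible character vector of the written file paths.
#' @export
write_dicom_series <- function(vol, dir, patient_name = "PHANTOM^CASE",
                               patient_id = "EPT-000",
                               series_uid = "1.2.826.0.1.3680043.9999.2") {
  stopifnot(inherits(vol, "ept_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$voxels)
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    sl <- vol$voxels[, , k]
    pix <- as.integer(round(sl))  # column-major = x fastest, matching layout
    pos <- vol$origin + c(0, 0, (k - 1) * vol$spacing[3])
    elements <- list(
      list(group = 0x0008, elem = 0x0016, vr = "UI",
           value = "1.2.840.10008.5.1.4.1.1.2"),
      list(group = 0x0008, elem = 0x0018, vr = "UI",
           value = sprintf("%s.%d", series_uid, k)),
      list(group = 0x0008, elem = 0x0060, vr = "CS", value = vol$modality),
      list(group = 0x0008, elem = 0x0080, vr = "LO", value = "EPT Institute"),
      list(group = 0x0008, elem = 0x0090, vr = "PN", value = "DOC^REF"),
      list(group = 0x0010, elem = 0x0010, vr = "PN", value = patient_name),
      list(group = 0x0010, elem = 0x0020, vr = "LO", value = patient_id),
      list(group = 0x0010, elem = 0x0030, vr = "DA", value = "19700101"),
      list(group = 0x0020, elem = 0x000D, vr = "UI",
           value = paste0(series_uid, ".study")),
      list(group = 0x0020, elem = 0x000E, vr = "UI", value = series_uid),
      list(group = 0x0020, elem = 0x0013, vr = "IS", value = as.character(k)),
      list(group = 0x0020, elem = 0x0032, vr = "DS",
           value = sprintf("%.6f", pos)),
      list(group = 0x0020, elem = 0x0037, vr = "DS",
           value = sprintf("%.1f", c(1, 0, 0, 0, 1, 0))),
      list(group = 0x0028, elem = 0x0002, vr = "US", value = 1),
      list(group = 0x0028, elem = 0x0010, vr = "US", value = d[2]), # Rows
      list(group = 0x0028, elem = 0x0011, vr = "US", value = d[1]), # Columns
      list(group = 0x0028, elem = 0x0030, vr = "DS",
           value = sprintf("%.6f", c(vol$spacing[2], vol$spacing[1]))),
      list(group = 0x0018, elem = 0x0050, vr = "DS",
           value = sprintf("%.6f", vol$spacing[3])),
      list(group = 0x0028, elem = 0x0100, vr = "US", value = 16),
      list(group = 0x0028, elem = 0x0101, vr = "US", value = 16),
      list(group = 0x0028, elem = 0x0102, vr = "US", value = 15),
      list(group = 0x0028, elem = 0x0103, vr = "US", value = 1),
      list(group = 0x0028, elem = 0x1052, vr = "DS", value = "0"),
      list(group = 0x0028, elem = 0x1053, vr = "DS", value = "1"),
      list(group = 0x7FE0, elem = 0x0010, vr = "OW",
           value = writeBin(pix, raw(), size = 2, endian = "little")))
    paths[k] <- file.path(dir, sprintf("slice_%04d.dcm", k))
    dcm_write_file(paths[k], elements)
  }
  invisible(paths)
}

#' Read a single-series axial DICOM stack into a volume
#'
#' Slices are sorted by the projection of ImagePositionPatient onto the slice
#' normal (file order on disk is irrelevant); rescale slope/intercept is
#' applied. Mixed series UIDs, inconsistent in-plane dimensions, or missing
#' spacing tags are errors.
#'
#' @param path directory containing the `.dcm` files of one series.
#' @return an [image_volume()].
#' @export
read_dicom_series <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0) stop("no DICOM files in ", path)
  parsed <- lapply(files, dcm_parse_file)
  uids <- vapply(parsed, function(e) {
    u <- dcm_get_str(e, 0x0020, 0x000E)
    if (is.null(u)) "" else u
  }, "")
  if (length(unique(uids)) != 1)
    stop("directory mixes multiple series UIDs: ",
         paste(unique(uids), collapse = ", "))
  rows <- vapply(parsed, function(e) dcm_get_num(e, 0x0028, 0x0010), 0)
  cols <- vapply(parsed, function(e) dcm_get_num(e, 0x0028, 0x0011), 0)
  if (length(unique(rows)) != 1 || length(unique(cols)) != 1)
    stop("inconsistent in-plane dimensions across slices")
  ps <- dcm_get_num(parsed[[1]], 0x0028, 0x0030)
  if (is.null(ps)) stop("missing PixelSpacing tag (0028,0030)")
  orient <- dcm_get_num(parsed[[1]], 0x0020, 0x0037)
  if (is.null(orient)) orient <- c(1, 0, 0, 0, 1, 0)
  normal <- c(orient[2] * orient[6] - orient[3] * orient[5],
              orient[3] * orient[4] - orient[1] * orient[6],
              orient[1] * orient[5] - orient[2] * orient[4])
  posns <- lapply(parsed, function(e) dcm_get_num(e, 0x0020, 0x0032))
  if (any(vapply(posns, is.null, TRUE)))
    stop("missing ImagePositionPatient tag (0020,0032)")
  proj <- vapply(posns, function(p) sum(p * normal), 0)
  ord <- order(proj)
  parsed <- parsed[ord]; posns <- posns[ord]; proj <- proj[ord]
  nz <- length(parsed)
  dz <- if (nz > 1) stats::median(diff(proj)) else {
    st <- dcm_get_num(parsed[[1]], 0x0018, 0x0050)
    if (is.null(st)) stop("missing SliceThickness tag (0018,0050)")
    st
  }
  if (!is.finite(dz) || dz <= 0) stop("cannot determine slice spacing")
  nx <- as.integer(cols[1]); ny <- as.integer(rows[1])
  vox <- array(0, c(nx, ny, nz))
  modality <- dcm_get_str(parsed[[1]], 0x0008, 0x0060)
  if (is.null(modality) || !modality %in% c("CT", "MRI", "MR")) modality <- "CT"
  if (modality == "MR") modality <- "MRI"
  for (k in seq_len(nz)) {
    e <- parsed[[k]]
    i <- dcm_find(e, 0x7FE0, 0x0010)
    if (is.null(i)) stop("missing PixelData in slice ", k)
    signed <- isTRUE(dcm_get_num(e, 0x0028, 0x0103) == 1)
    pix <- readBin(e[[i]]$raw, "integer", n = nx * ny, size = 2,
                   endian = "little", signed = signed)
    slope <- dcm_get_num(e, 0x0028, 0x1053)
    inter <- dcm_get_num(e, 0x0028, 0x1052)
    if (!is.null(slope)) pix <- pix * slope
    if (!is.null(inter)) pix <- pix + inter
    vox[, , k] <- pix
  }
  image_volume(vox, spacing = c(ps[2], ps[1], dz), origin = posns[[1]],
               modality = modality)
}

#' Anonymize DICOM files
#'
#' Removes the elements named by `policy` (default:
#' [default_anonymize_policy()]) from every DICOM file under `src`, writing
#' results to `dst`. Pixel data and geometry tags are untouched; running the
#' anonymizer on its own output removes nothing (idempotent).
#'
#' @param src source file or directory.
#' @param dst destination file or directory.
#' @param policy list of `c(group, element)` tag pairs to remove.
#' @param overwrite allow writing into an existing destination.
#' @return total number of elements removed (invisible count per file summed).
#' @export
anonymize_dicom <- function(src, dst, policy = default_anonymize_policy(),
                            overwrite = FALSE) {
  if (dir.exists(src)) {
    if (dir.exists(dst) && !overwrite &&
        length(list.files(dst, pattern = "\\.dcm$")) > 0)
      stop("destination exists; pass overwrite = TRUE")
    dir.create(dst, showWarnings = FALSE, recursive = TRUE)
    files <- list.files(src, pattern = "\\.dcm$", full.names = FALSE,
                        ignore.case = TRUE)
    return(sum(vapply(files, function(f)
      anonymize_dicom(file.path(src, f), file.path(dst, f), policy,
                      overwrite = TRUE), 0)))
  }
  if (file.exists(dst) && !overwrite)
    stop("destination exists; pass overwrite = TRUE")
  elements <- dcm_parse_file(src)
  keep <- vapply(elements, function(e) {
    !any(vapply(policy, function(p)
      e$group == p[1] && e$elem == p[2], TRUE))
  }, TRUE)
  removed <- as.numeric(sum(!keep))
  elements <- elements[keep]
  # rewrite verbatim (meta group elements already include transfer syntax)
  body <- do.call(c, lapply(
    elements[vapply(elements, function(e) e$group != 0x0002, TRUE)],
    function(e) dcm_element_raw(e$group, e$elem, e$vr,
                                if (e$vr %in% c("US", "SS", "UL"))
                                  readBin(e$raw, "integer",
                                          n = length(e$raw) / ifelse(e$vr == "UL", 4, 2),
                                          size = ifelse(e$vr == "UL", 4, 2),
                                          endian = "little",
                                          signed = e$vr == "SS")
                                else if (e$vr == "OW") e$raw
                                else dcm_raw_to_str(e$raw))))
  meta <- elements[vapply(elements, function(e)
    e$group == 0x0002 && e$elem != 0x0000, TRUE)]
  meta_raw <- do.call(c, lapply(meta, function(e)
    dcm_element_raw(e$group, e$elem, e$vr, dcm_raw_to_str(e$raw))))
  grouplen <- dcm_element_raw(0x0002, 0x0000, "UL", length(meta_raw))
  con <- file(dst, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(grouplen, meta_raw, body), con)
  removed
}
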