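small_phantom <- function() {
  generate_abdomen_phantom(
    phantom_spec(shape = c(16, 20, 10), spacing = c(1, 1.5, 3), noise_sd = 0))
}

test_that("NIfTI volume and mask round-trips are exact", {
  ph <- small_phantom()
  td <- withr::local_tempdir()
  p <- file.path(td, "v.nii")
  write_volume(ph$volume, p)
  v2 <- read_volume(p)
  expect_identical(v2$voxels, ph$volume$voxels)
  expect_equal(v2$spacing, c(1, 1.5, 3))
  expect_equal(v2$origin, ph$volume$origin)

  pm <- file.path(td, "m.nii")
  write_mask(ph$truth, pm)
  m2 <- read_mask(pm)
  expect_identical(m2$labels, ph$truth$labels)
  expect_identical(m2$label_table, ph$truth$label_table)
  expect_equal(m2$spacing, c(1, 1.5, 3))
})

test_that("NRRD masks are accepted on read", {
  ph <- small_phantom()
  td <- withr::local_tempdir()
  p <- file.path(td, "m.nrrd")
  con <- file(p, "wb")
  writeLines(c("NRRD0004", "type: int", "dimension: 3",
               sprintf("sizes: %s", paste(dim(ph$truth$labels), collapse = " ")),
               "encoding: raw",
               "space directions: (1,0,0) (0,1.5,0) (0,0,3)",
               "space origin: (0,0,0)", ""), con)
  writeBin(as.integer(ph$truth$labels), con, size = 4, endian = "little")
  close(con)
  m <- read_mask(p)
  expect_identical(m$labels, ph$truth$labels)
  expect_equal(m$spacing, c(1, 1.5, 3))
})

test_that("DICOM series round-trips, sorts by position, validates", {
  ph <- small_phantom()
  td <- withr::local_tempdir()
  dd <- file.path(td, "dcm")
  write_dicom_series(ph$volume, dd)
  v <- read_dicom_series(dd)
  expect_identical(v$voxels, ph$volume$voxels)
  expect_equal(v$spacing, ph$volume$spacing)

  # shuffled file names still yield the position-sorted volume
  dd2 <- file.path(td, "shuffled")
  dir.create(dd2)
  fs <- list.files(dd, full.names = TRUE)
  file.copy(fs, file.path(dd2, sprintf("%s.dcm", rev(letters[seq_along(fs)]))))
  v2 <- read_dicom_series(dd2)
  expect_identical(v2$voxels, ph$volume$voxels)

  # two series mixed in one directory is an error
  write_dicom_series(ph$volume, dd2, series_uid = "1.2.826.0.1.3680043.9999.77")
  expect_error(read_dicom_series(dd2), "series UIDs")
})

test_that("anonymization strips policy tags, is idempotent, keeps pixels", {
  ph <- small_phantom()
  td <- withr::local_tempdir()
  dd <- file.path(td, "dcm")
  write_dicom_series(ph$volume, dd)
  ad <- file.path(td, "anon")
  n1 <- anonymize_dicom(dd, ad)
  # 5 policy tags present per written slice (name, id, birth date,
  # referring physician, institution)
  expect_equal(n1, 5 * dim(ph$volume$voxels)[3])
  n2 <- anonymize_dicom(ad, file.path(td, "anon2"))
  expect_equal(n2, 0)
  v <- read_dicom_series(ad)
  expect_identical(v$voxels, ph$volume$voxels)
  expect_error(anonymize_dicom(dd, ad), "overwrite")
})

test_that("volume/mask constructors enforce their invariants", {
  expect_error(image_volume(array(0, c(4, 4, 2)), c(1, 1, 1)), "at least")
  expect_error(image_volume(array(c(NA, rep(0, 8 * 8 * 3 - 1)), c(8, 8, 3)),
                            c(1, 1, 1)), "finite")
  expect_error(image_volume(array(0, c(8, 8, 3)), c(1, -1, 1)), "spacing")
  expect_error(label_mask(array(2L, c(8, 8, 3)), c(1, 1, 1),
                          label_table = c(a = 1L)), "not in label table")
})
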