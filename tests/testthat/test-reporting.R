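demo_bundle <- function() fixture("demo_bundle", function() {
  sc <- solver_case()
  plan <- optimize_pair_voltages(sc$truth, sc$elec, sc$array, sc$props,
                                 pulse_protocol("ECT"), delta_u = 100)
  treatment_plan_bundle("demo", sc$volume, sc$truth, sc$array, plan,
                        pulse_protocol("ECT"))
})

test_that("field overlay: transparency at zero field, dims, iso-contour", {
  sc <- solver_case()
  d <- dim(sc$volume$voxels)
  zero <- array(0, d)
  img <- overlay_field_slice(sc$volume, zero, 10, c(400, 800))
  base <- sc$volume$voxels[, , 10]
  gray <- (base - min(base)) / diff(range(base))
  for (ch in 1:3) expect_equal(img[, , ch], gray, tolerance = 1e-12)

  img2 <- overlay_field_slice(sc$volume, zero, 10, c(400, 800), scale = 3L)
  expect_equal(dim(img2), c(d[1] * 3, d[2] * 3, 3))
  expect_error(overlay_field_slice(sc$volume, zero, 999, c(400, 800)),
               "out of range")

  # synthetic step field: the iso-line encloses exactly the voxels >= level
  E <- array(0, d); E[10:20, 10:20, 10] <- 600
  line <- eptplan:::threshold_isocontour(E[, , 10], 400)
  filled <- eptplan:::fill_holes(array(line, c(d[1], d[2], 1)))[, , 1]
  expect_identical(filled, E[, , 10] >= 400)
})

test_that("treatment report: panels, table sizes, determinism", {
  b <- demo_bundle()
  td <- withr::local_tempdir()
  p1 <- file.path(td, "r1.html")
  render_treatment_report(b, p1)
  h <- readLines(p1)
  for (sec in c("model-views", "voltage-table", "coverage-curves",
                "field-overlays", "treated-volumes"))
    expect_true(any(grepl(paste0("SECTION:", sec), h)), info = sec)
  # one voltage row per pair
  expect_equal(sum(grepl("<tr><td>\\d+</td><td>\\d+-\\d+</td>", h)),
               nrow(b$plan$pairs))
  # report numbers equal the bundle values exactly
  expect_true(any(grepl(sprintf("<td>%g</td>", b$plan$voltages[1]), h)))
  p2 <- file.path(td, "r2.html")
  render_treatment_report(b, p2)
  expect_identical(readLines(p2), h)  # byte-deterministic

  render_treatment_report(b, file.path(td, "r3.html"), formats = c("html",
                                                                   "pdf"))
  expect_true(file.exists(file.path(td, "r3.pdf")))
})

test_that("run_procedure: full pipeline, dependency check, stage cache", {
  sp <- phantom_spec(shape = c(40, 40, 24), spacing = c(2.5, 2.5, 2.5),
                     noise_sd = 0, tumor_radius = 8)
  td <- withr::local_tempdir()
  cfg <- list(case_id = "smoke", outdir = file.path(td, "case"), stages = list(
    list(name = "phantom", spec = sp),
    list(name = "electrodes", electrode_id = "variable-single",
         entry = c(sp$tumor_center[1:2], 0), target_point = sp$tumor_center,
         n = 2, needle_spacing = 14, active_length = 20),
    list(name = "plan", protocol_mode = "ECT", delta_u = 100),
    list(name = "report", path = file.path(td, "report.html"))))
  msgs1 <- capture_messages(b <- run_procedure(cfg))
  expect_s3_class(b, "treatment_plan_bundle")
  expect_true(file.exists(file.path(td, "report.html")))
  expect_true(any(grepl("\\[plan\\] done", msgs1)))

  # re-run: everything served from the stage cache
  msgs2 <- capture_messages(run_procedure(cfg))
  expect_true(all(grepl("cached", grep("^\\[", msgs2, value = TRUE))))

  expect_error(run_procedure(list(stages = list(list(name = "plan")))),
               "requires 'tissue'")
  expect_error(run_procedure(list(stages = list(list(name = "warp")))),
               "unknown stage")
})

test_that("CLI: phantom subcommand writes volume and truth", {
  td <- withr::local_tempdir()
  out <- file.path(td, "ph")
  status <- eptplan_cli(c("phantom", "--shape", "32,32,16", "--spacing",
                          "3,3,3", "--out", out, "--seed", "5"))
  expect_true(file.exists(paste0(out, "_volume.nii")))
  v <- read_volume(paste0(out, "_volume.nii"))
  expect_equal(dim(v$voxels), c(32, 32, 16))
  m <- read_mask(paste0(out, "_truth.nii"))
  expect_true("liver" %in% names(m$label_table))
  expect_equal(eptplan_cli(character(0)), 1L, ignore_attr = TRUE)
})

test_that("array/plan/curve serializations round-trip", {
  td <- withr::local_tempdir()
  sc <- solver_case()
  ap <- file.path(td, "arr.json")
  write_array_json(sc$array, ap)
  arr2 <- read_array_json(ap)
  expect_equal(arr2$tips, sc$array$tips, tolerance = 1e-9)
  expect_identical(arr2$pairs, sc$array$pairs)
  expect_identical(arr2$spec$id, sc$array$spec$id)

  b <- demo_bundle()
  pp <- file.path(td, "plan.json")
  write_plan_json(b$plan, pp)
  doc <- jsonlite::read_json(pp)
  expect_equal(doc$coverage, b$plan$coverage)
  expect_equal(as.numeric(unlist(doc$voltages)), b$plan$voltages)

  cp <- file.path(td, "cc.csv")
  write_curve_csv(b$curves[[b$plan$target]], cp)
  cc <- utils::read.csv(cp)
  expect_equal(cc$fraction, b$curves[[b$plan$target]]$fraction)
})
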