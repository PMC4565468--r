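circle_contour <- function(n = 100, r = 10, c0 = c(20, 20), slice = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  slice_contour(cbind(c0[1] + r * cos(th), c0[2] + r * sin(th)), slice)
}

test_that("contour extraction: area, multiplicity, empty cases", {
  lab <- array(0L, c(20, 20, 3))
  lab[6:15, 6:15, 2] <- 1L
  m <- label_mask(lab, c(1, 1, 1))
  cs <- extract_slice_contours(m, 1L)
  expect_length(cs, 1)
  expect_equal(cs[[1]]$slice, 2L)
  # shoelace area within 1 px^2 of the pixel count
  expect_lt(abs(abs(eptplan:::shoelace(cs[[1]]$points)) - 100), 1)
  # counterclockwise orientation
  expect_gt(eptplan:::shoelace(cs[[1]]$points), 0)

  expect_length(extract_slice_contours(m, 5L), 0)

  lab2 <- array(0L, c(30, 30, 1))
  lab2[3:8, 3:8, 1] <- 1L
  lab2[20:25, 20:25, 1] <- 1L
  cs2 <- extract_slice_contours(label_mask(lab2, c(1, 1, 1)), 1L)
  expect_length(cs2, 2)
})

test_that("point influence: collinearity, corners, scaling", {
  sq <- rbind(c(0, 0), c(0, 5), c(0, 10), c(5, 10), c(10, 10), c(10, 5),
              c(10, 0), c(5, 0))
  infl <- point_influence(slice_contour(sq, 1))
  corners <- c(1, 3, 5, 7); mids <- c(2, 4, 6, 8)
  expect_true(all(infl[mids] < 1e-12))          # collinear -> 0
  expect_true(min(infl[corners]) > max(infl[mids]))
  expect_equal(point_influence(slice_contour(sq * 2, 1)), 2 * infl)
  dup <- rbind(c(0, 0), c(0, 0), c(1, 1), c(0, 1))
  expect_error(point_influence(slice_contour(dup, 1)), "duplicate")
})

test_that("simplification: default percent, subset property, corners", {
  sc <- circle_contour(100)
  s <- simplify_contour(sc, 20)
  expect_equal(nrow(s$points), 20)
  # retained points are a subset of the originals, order preserved
  idx <- match(apply(s$points, 1, paste, collapse = ","),
               apply(sc$points, 1, paste, collapse = ","))
  expect_false(anyNA(idx))
  expect_true(all(diff(idx) > 0))

  n_side <- 25
  side <- function(p, q) cbind(seq(p[1], q[1], length.out = n_side + 1),
                               seq(p[2], q[2], length.out = n_side + 1))[
                                 -(n_side + 1), ]
  poly <- rbind(side(c(0, 0), c(0, 10)), side(c(0, 10), c(10, 10)),
                side(c(10, 10), c(10, 0)), side(c(10, 0), c(0, 0)))
  s4 <- simplify_contour(slice_contour(poly, 1), 4)
  expect_equal(nrow(s4$points), 4)
  expect_true(all(s4$points %in% c(0, 10)))

  expect_error(simplify_contour(circle_contour(10), 5), "fewer than 3")
})

test_that("simplification properties: convex inputs stay simple, area stable", {
  set.seed(42)
  for (trial in 1:10) {
    n <- sample(30:80, 1)
    th <- sort(stats::runif(n, 0, 2 * pi))
    r <- 8 + stats::rnorm(1, 0, 1)
    pts <- cbind(20 + r * cos(th), 20 + r * sin(th))  # convex (circle arc)
    s <- simplify_contour(slice_contour(pts, 1), 25)
    expect_true(eptplan:::contour_is_simple(s$points))
  }
  # area change <= 2% at 20% retention on smooth contours
  for (n in c(100, 150)) {
    sc <- circle_contour(n, r = 12)
    s <- simplify_contour(sc, 20)
    a0 <- abs(eptplan:::shoelace(sc$points))
    expect_lt(abs(abs(eptplan:::shoelace(s$points)) - a0) / a0, 0.02)
  }
})

test_that("refinement: identity path, exact interpolation, locality", {
  sc <- circle_contour(40, r = 10, c0 = c(20, 20))
  expect_identical(refine_contour(sc, 20)$points,
                   simplify_contour(sc, 20)$points)

  ed <- apply_contour_edit(sc, list(op = "move_point", point = 5,
                                    to = c(27, 29)))
  rf <- refine_contour(ed, 60)
  expect_true(any(rf$points[, 1] == 27 & rf$points[, 2] == 29))
  # deviation from the analytic circle only near the edited span
  dev <- abs(sqrt(rowSums(sweep(rf$points, 2, c(20, 20))^2)) - 10)
  far <- rf$points[dev > 1.5, , drop = FALSE]
  if (nrow(far))
    expect_true(all(sqrt(rowSums(sweep(far, 2, c(27, 29))^2)) < 8))
  expect_error(apply_contour_edit(sc, list(op = "move_point", point = 99,
                                           to = c(0, 0))), "does not exist")
})

test_that("rasterization: pixel-center fill, round trip, validation", {
  sq <- rbind(c(-0.5, -0.5), c(-0.5, 9.5), c(9.5, 9.5), c(9.5, -0.5))
  mk <- rasterize_contours(list(slice_contour(sq, 1)), c(20, 20, 3))
  expect_true(abs(sum(mk$labels > 0L) - 100) <= 4)

  expect_equal(sum(rasterize_contours(list(), c(10, 10, 2))$labels), 0)

  bow <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(rasterize_contours(list(slice_contour(bow, 3)),
                                  c(20, 20, 3)), "slice 3")

  # mask -> contours -> mask on a smooth blob
  lab <- array(0L, c(40, 40, 5))
  ij <- expand.grid(i = 1:40, j = 1:40)
  for (k in 2:4) {
    r <- 12 - 2 * abs(k - 3)
    sl <- matrix((ij$i - 20)^2 + (ij$j - 20)^2 <= r^2, 40, 40)
    lab[, , k][sl] <- 1L
  }
  m <- label_mask(lab, c(1, 1, 1))
  m2 <- rasterize_contours(extract_slice_contours(m, 1L), dim(lab))
  expect_gte(dice(m$labels > 0L, m2$labels > 0L), 0.99)

  # refine -> rasterize -> extract is stable to within one pixel
  cs2 <- extract_slice_contours(m2, 1L)
  for (cc in cs2) {
    orig <- Filter(function(x) x$slice == cc$slice,
                   extract_slice_contours(m, 1L))[[1]]
    d <- vapply(seq_len(nrow(cc$points)), function(i)
      min(sqrt(rowSums(sweep(orig$points, 2, cc$points[i, ])^2))), 0)
    expect_lte(max(d), 1)
  }
})

test_that("manual ingest validates and rasterizes across slices", {
  doc <- list(objects = list(list(
    id = "t1", label = "tumor",
    slices = lapply(3:5, function(k)
      list(index = k, points = list(c(5, 5), c(5, 15), c(15, 10)))))))
  mi <- manual_contour_ingest(doc)
  expect_length(mi[["t1"]], 3)
  expect_true(all(mi[["t1"]][[1]]$flags == "user-moved"))
  mk <- rasterize_contours(mi[["t1"]], c(20, 20, 8))
  occupied <- which(apply(mk$labels > 0L, 3, any))
  expect_equal(occupied, 3:5)

  bad <- list(objects = list(list(id = "x", slices = list(
    list(index = 1, points = list(c(0, 0), c(5, 5)))))))
  expect_error(manual_contour_ingest(bad), "fewer than 3")
  degen <- list(objects = list(list(id = "x", slices = list(
    list(index = 1, points = list(c(0, 0), c(5, 5), c(10, 10)))))))
  expect_error(manual_contour_ingest(degen), "degenerate")

  tf <- withr::local_tempfile(fileext = ".json")
  write_contours_json(mi, tf)
  mi2 <- manual_contour_ingest(tf)
  expect_equal(mi[["t1"]][[2]]$points, mi2[["t1"]][[2]]$points)
})
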