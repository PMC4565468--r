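test_that("protocols: standard constants, unknown settings rejected", {
  ect <- pulse_protocol("ECT")
  expect_equal(ect$pulses, 8L)
  expect_equal(ect$duration_us, 100)
  expect_equal(ect$frequency_hz, 1)
  ire <- pulse_protocol("IRE")
  expect_equal(ire$pulses, 90L)

  th <- protocol_thresholds(ect)
  expect_true(all(c("liver", "tumor") %in% th$tissue))
  expect_true(all(th$e_rev <= th$e_irr))
  expect_error(protocol_thresholds(pulse_protocol("ECT", pulses = 4)),
               "no calibrated thresholds")
})

test_that("sigma(E): plateaus, midpoint, monotone max-rule", {
  d <- c(8, 8, 4)
  lab <- label_mask(array(1L, d), c(1, 1, 1), label_table = c(liver = 1L))
  props <- tissue_properties()
  p <- props$liver
  s_lo <- sigma_of_E(array(0, d), lab, props)
  expect_true(all(s_lo == p$sigma0))
  s_hi <- sigma_of_E(array(p$e_high + 100, d), lab, props)
  expect_true(all(s_hi == p$sigma_max))
  mid <- (p$e_low + p$e_high) / 2
  s_mid <- sigma_of_E(array(mid, d), lab, props)
  expect_equal(s_mid[1], (p$sigma0 + p$sigma_max) / 2)
  # monotone in E
  es <- seq(0, p$e_high * 1.5, length.out = 40)
  sv <- vapply(es, function(e) sigma_of_E(array(e, d), lab, props)[1], 0)
  expect_true(all(diff(sv) >= 0))
  # unlabeled voxel is an error
  lab2 <- label_mask(array(c(9L, rep(1L, prod(d) - 1)), d), c(1, 1, 1),
                     label_table = c(liver = 1L, mystery = 9L))
  expect_error(sigma_of_E(array(0, d), lab2, props), "no tissue properties")
})

test_that("linear solve: plate field, maximum principle, linearity", {
  n <- 24; d <- c(n, n, 6)
  sigma <- array(0.2, d)
  elec <- array(0L, d); elec[1, , ] <- 1L; elec[n, , ] <- 2L
  U <- 100
  u <- solve_pair(sigma, elec, c(1, 2), U, c(1, 1, 1))
  E <- field_magnitude(u, c(1, 1, 1))
  exact <- U / ((n - 1) * 0.1)  # V/cm over (n-1) mm
  interior <- E[5:(n - 5), 5:(n - 5), 2:5]
  expect_lt(max(abs(interior - exact)) / exact, 0.01)
  expect_gte(min(u), 0)
  expect_lte(max(u), U)
  u2 <- solve_pair(sigma, elec, c(1, 2), 2 * U, c(1, 1, 1))
  expect_equal(2 * as.vector(u), as.vector(u2), tolerance = 1e-12)
  expect_error(solve_pair(sigma, elec, c(1, 5), U, c(1, 1, 1)),
               "no electrode voxels")
})

test_that("field magnitude: linear, constant, quadratic potentials", {
  d <- c(20, 12, 6)
  x_mm <- array(rep((seq_len(d[1]) - 1) * 1, times = d[2] * d[3]), d)
  # u = x: 1 V/mm = 10 V/cm everywhere (one-sided edges included)
  E <- field_magnitude(x_mm, c(1, 1, 1))
  expect_equal(as.vector(E), rep(10, prod(d)), tolerance = 1e-12)
  expect_true(all(field_magnitude(array(5, d), c(1, 1, 1)) == 0))
  # u = x^2: |grad| = 2x, central differences exact for quadratics
  E2 <- field_magnitude(x_mm^2, c(1, 1, 1))
  interior <- 2:(d[1] - 1)
  expect_equal(as.vector(E2[interior, 1, 1]),
               10 * 2 * (interior - 1), tolerance = 1e-9)
})

test_that("grid convergence on the coaxial-cylinder solution", {
  errs <- vapply(c(32, 64, 128), function(n) {
    sc <- n / 128
    cs <- coax_system(n = n, a = 10 * sc, b = 55 * sc, nz = 3)
    h <- 1 / sc  # physical geometry fixed, resolution varies
    sigma <- array(0.3, cs$dim)
    u <- solve_pair(sigma, cs$elec, c(1, 2), 1000, c(h, h, h))
    E <- field_magnitude(u, c(h, h, h))
    rmid_vox <- (cs$a + cs$b) / 2
    sel <- abs(cs$r2d - rmid_vox) < 0.5
    exact <- 1000 / ((rmid_vox * h / 10) * log(cs$b / cs$a))
    abs(mean(E[, , 2][sel]) - exact) / exact
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.03)
})

test_that("nonlinear iteration: monotone sigma, bounds, degenerate case", {
  sc <- solver_case()
  props <- sc$props
  sig0 <- baseline_sigma(sc$truth, props)
  # manual two-step iteration to observe monotonicity voxelwise
  u1 <- solve_pair(sig0, sc$elec, c(1, 2), 1500, sc$truth$spacing)
  E1 <- field_magnitude(u1, sc$truth$spacing)
  s1 <- pmax(sig0, sigma_of_E(E1, sc$truth, props))
  expect_true(all(s1 >= sig0))
  res <- solve_nonlinear_pair(sig0, sc$elec, c(1, 2), 1500, sc$truth, props,
                              sc$truth$spacing)
  expect_true(res$converged)
  expect_lte(res$iterations, 20)
  smax_grid <- eptplan:::tissue_lookup(sc$truth$labels,
                                       sc$truth$label_table, props,
                                       "sigma_max")
  expect_true(all(res$sigma <= smax_grid + 1e-12))
  expect_true(all(res$sigma >= sig0))
  # field adjacent to a needle exceeds the inter-needle midpoint field
  # (probe one voxel beyond the needle surface along the pair axis)
  w <- which(sc$elec == 1L, arr.ind = TRUE)
  zmid <- round(mean(range(w[, 3])))
  wz <- w[w[, 3] == zmid, , drop = FALSE]
  near <- wz[which.max(wz[, 2]), ] + c(0, 1, 0)
  mid_idx <- round(sc$spec$tumor_center / sc$truth$spacing) + 1
  expect_gt(res$E[near[1], near[2], near[3]],
            res$E[mid_idx[1], mid_idx[2], zmid])

  lp <- linear_props()
  res_lin <- solve_nonlinear_pair(baseline_sigma(sc$truth, lp), sc$elec,
                                  c(1, 2), 1500, sc$truth, lp,
                                  sc$truth$spacing)
  expect_equal(res_lin$iterations, 1L)
  u_ref <- solve_pair(baseline_sigma(sc$truth, lp), sc$elec, c(1, 2), 1500,
                      sc$truth$spacing)
  expect_identical(unclass(res_lin$potential), unclass(u_ref))
})

test_that("sequence: cumulative max map and order robustness", {
  # two-pair geometry that is mirror-symmetric on the voxel lattice, so
  # reversing the pulse order must leave the cumulative max-field map
  # (essentially) unchanged
  sp <- phantom_spec(shape = c(40, 41, 24), spacing = c(2.5, 2.5, 2.5),
                     noise_sd = 0, tumor_radius = 8,
                     liver_center = c(48.75, 50, 28.75),
                     tumor_center = c(56.75, 50, 28.75))
  ph <- generate_abdomen_phantom(sp)
  truth <- ph$truth
  props <- tissue_properties()
  spec <- electrode_spec_by_id("variable-single")
  ctr <- sp$tumor_center
  arr3 <- place_parallel_array(spec, entry = c(ctr[1], ctr[2], 0),
                               target = ctr, n = 3, spacing = 12.5,
                               active_length = 20)
  elec3 <- rasterize_electrodes(arr3, dim(truth$labels), truth$spacing,
                                truth$origin)
  fs <- solve_sequence(truth, elec3, arr3, c(1200, 1200), props)
  for (p in fs$per_pair)
    expect_true(all(fs$E_max >= p$E - 1e-9))
  arr3r <- arr3
  arr3r$pairs <- arr3$pairs[2:1, , drop = FALSE]
  fsr <- solve_sequence(truth, elec3, arr3r, c(1200, 1200), props)
  # with carried conductivity the reversed-order map is the exact mirror
  # image of the forward-order map (solver is symmetric to machine
  # precision); the map itself is order-dependent because the sigma
  # history differs
  expect_lt(max(abs(fs$E_max[, rev(seq_len(41)), ] - fsr$E_max)), 1e-6)
  # with per-pair conductivity reset the cumulative map is strictly
  # order-invariant: < 1% voxelwise (in fact near machine precision)
  fs_i <- solve_sequence(truth, elec3, arr3, c(1200, 1200), props,
                         reset_sigma_per_pair = TRUE)
  fsr_i <- solve_sequence(truth, elec3, arr3r, c(1200, 1200), props,
                          reset_sigma_per_pair = TRUE)
  denom <- pmax(fs_i$E_max, 0.05 * max(fs_i$E_max))
  expect_lt(max(abs(fs_i$E_max - fsr_i$E_max) / denom), 0.01)

  # single pair: cumulative equals the pair map
  sc <- solver_case()
  fs1 <- solve_sequence(sc$truth, sc$elec, sc$array, 1200, sc$props)
  expect_equal(fs1$E_max, fs1$per_pair[[1]]$E)
})
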