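test_that("wrap_to_pi lands in (-pi, pi], is idempotent and 2*pi-periodic", {
  expect_equal(wrap_to_pi(0), 0)
  expect_equal(wrap_to_pi(3 * pi), pi)
  expect_equal(wrap_to_pi(-pi), pi)    # half-open boundary convention
  expect_equal(wrap_to_pi(pi), pi)
  set.seed(2)
  x <- runif(500, -30, 30)
  w <- wrap_to_pi(x)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(wrap_to_pi(w), w)                       # idempotent
  for (k in c(-3, -1, 2, 5))
    expect_equal(wrap_to_pi(x + 2 * pi * k), w, tolerance = 1e-9)
  expect_error(wrap_to_pi(c(1, NaN)), "finite")
})

test_that("constant wrapped phase unwraps to a constant in Hz with zero wraps", {
  g <- grid3d(c(6, 5, 4), 5)
  cph <- 1.2
  acq <- wrapped_acquisition(array(cph, g$shape), array(1, g$shape), 0.002, g)
  m <- region_growing_unwrap(acq, 0.1)
  expect_true(all(m$valid_mask))
  expect_equal(m$values_hz, array(cph / (2 * pi * 0.002), g$shape))
  expect_true(all(m$wrap_count == 0L))
})

test_that("a 1D ramp below the Nyquist step matches sequential unwrapping", {
  g <- grid3d(c(64, 1, 1), 2, origin_mm = c(-63, 0, 0))
  true_phase <- 2.2 * (0:63)          # 2.2 rad/voxel < pi
  wrapped <- wrap_to_pi(true_phase)
  acq <- wrapped_acquisition(array(wrapped, g$shape),
                             array(1, g$shape), 0.002, g)
  m <- region_growing_unwrap(acq, 0.1)
  oracle <- brute_unwrap_1d(wrapped)
  expect_equal(as.vector(m$values_hz) * 2 * pi * 0.002, oracle,
               tolerance = 1e-12)
  expect_equal(as.vector(m$values_hz) * 2 * pi * 0.002, true_phase,
               tolerance = 1e-12)
})

test_that("wrap -> unwrap round trip recovers a smooth field up to a global branch", {
  scene <- tiny_implant_scene(85, shape = c(24, 24, 20), voxel = 4,
                              strength = 4e8)
  f <- scene_offresonance(scene, c(0, 0, 0))
  a <- acquire_static(scene, c(0, 0, 0), noise_free_acq())
  m <- region_growing_unwrap(a, 0.1)
  # assess the Nyquist-compliant neighbourhood of the target (per-neighbour
  # phase steps < pi there); the aliased shell hugging the implant void has
  # no recoverable phase by construction
  probe <- sphere_mask(target_sphere(c(0, 0, 0), 30), c(0, 0, 0), scene$grid)
  sel <- probe & m$valid_mask
  err <- (m$values_hz - f$values_hz)[sel]
  off <- median(err)
  expect_equal((off * 0.002) %% 1, 0, tolerance = 1e-9)  # integer branches
  expect_lt(max(abs(err - off)), 1e-6)
  # the target region does contain wraps, so the test is not vacuous
  expect_gte(wraps_in_region(m, probe), 1L)
})

test_that("unwrapped minus wrapped phase is an exact 2*pi multiple everywhere", {
  scene <- tiny_implant_scene(70, shape = c(20, 20, 16), voxel = 4)
  a <- acquire_static(scene, c(0, 0, 0),
                      acquisition_config(noise_sd = 0.02, seed = 9))
  m <- region_growing_unwrap(a, 0.1)
  k <- (m$values_hz * 2 * pi * m$delta_te_s - a$phase_rad) / (2 * pi)
  expect_equal(k[m$valid_mask], round(k[m$valid_mask]), tolerance = 1e-9)
  expect_equal(round(k[m$valid_mask]), as.numeric(m$wrap_count[m$valid_mask]))
  # unwrapping never alters magnitude or the void mask
  expect_identical(m$magnitude, a$magnitude)
  expect_identical(m$valid_mask,
                   array(a$magnitude >= 0.1 * max(a$magnitude), dim(a$magnitude)))
})

test_that("output is invariant to a global 2*pi shift of the input phase", {
  scene <- tiny_implant_scene(70, shape = c(16, 16, 12), voxel = 5)
  a <- acquire_static(scene, c(0, 0, 0),
                      acquisition_config(noise_sd = 0.01, seed = 4))
  a2 <- a
  a2$phase_rad <- wrap_to_pi(a$phase_rad + 2 * pi)
  m <- region_growing_unwrap(a, 0.1)
  m2 <- region_growing_unwrap(a2, 0.1)
  expect_equal(m$values_hz, m2$values_hz, tolerance = 1e-9)
  expect_equal(m$wrap_count, m2$wrap_count)
})

test_that("disconnected components are unwrapped independently from their own seeds", {
  g <- grid3d(c(9, 1, 1), 2, origin_mm = c(-8, 0, 0))
  phase <- array(c(1, 1, 1, 0, 0, 0, 2, 2, 2), g$shape)
  mag <- array(c(1, 0.9, 0.8, 0.01, 0.01, 0.01, 0.7, 0.95, 0.8), g$shape)
  acq <- wrapped_acquisition(phase, mag, 0.002, g)
  m <- region_growing_unwrap(acq, 0.1)
  expect_equal(as.vector(m$valid_mask),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_true(all(m$wrap_count == 0L))  # each component referenced to 0
  expect_error(region_growing_unwrap(
    wrapped_acquisition(phase, array(0, g$shape) + 0, 0.002, g)),
    "void")
  bad <- acq
  bad$phase_rad[1] <- NaN
  expect_error(region_growing_unwrap(bad), "NaN")
})

test_that("wrap counting in a region distinguishes none, one, and multiple wraps", {
  g <- grid3d(c(8, 8, 1), 2)
  region <- array(TRUE, g$shape)
  flat <- make_map(array(10, g$shape), g,
                   wraps = array(0L, g$shape))
  expect_identical(wraps_in_region(flat, region), 0L)
  two <- make_map(array(10, g$shape), g,
                  wraps = array(rep(c(0L, 1L), each = 32), g$shape))
  expect_identical(wraps_in_region(two, region), 1L)
  # region entirely void is indeterminate, not zero
  voidmap <- make_map(array(0, g$shape), g,
                      valid = array(FALSE, g$shape),
                      wraps = array(0L, g$shape))
  expect_identical(wraps_in_region(voidmap, region), NA_integer_)
  expect_error(wraps_in_region(flat, array(FALSE, g$shape)), "empty")
})

test_that("a strong close dipole drives multiple wraps through the target", {
  scene <- tiny_implant_scene(85, shape = c(36, 36, 28), voxel = 3)
  acq <- noise_free_acq()
  a <- acquire_static(scene, c(0, 0, 0), acq)
  m <- region_growing_unwrap(a, 0.1)
  roi <- sphere_mask(scene$target, c(0, 0, 0), scene$grid)
  got <- wraps_in_region(m, roi)
  # oracle: recompute the branch index per voxel from the ground-truth field
  truth <- scene_offresonance(scene, c(0, 0, 0))$values_hz
  sel <- roi & m$valid_mask
  k_true <- round(truth[sel] * acq$delta_te_s)
  expect_identical(got, length(unique(k_true)) - 1L)
  expect_gte(got, 2L)
})

test_that("branch re-referencing zeroes the modal wrap count without changing differences", {
  scene <- tiny_implant_scene(85, shape = c(24, 24, 20), voxel = 4)
  a <- acquire_static(scene, c(0, 0, 0),
                      acquisition_config(noise_sd = 0.02, seed = 2))
  m <- region_growing_unwrap(a, 0.1)
  r <- rereference_branch(m)
  k <- as.vector(r$wrap_count[r$valid_mask])
  tab <- table(k)
  expect_identical(as.integer(names(tab)[which.max(tab)]), 0L)
  d <- (m$values_hz - r$values_hz)[m$valid_mask]
  expect_equal(sd(d), 0, tolerance = 1e-12)        # pure global shift
  expect_equal((d[1] * m$delta_te_s) %% 1, 0, tolerance = 1e-9)
})
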