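test_that("dipole field matches the closed forms on axis, equator, magic angle", {
  g <- grid3d(c(21, 21, 21), 2)
  k <- 1e5
  # source 20 mm below isocenter: isocenter voxel (11,11,11) is on-axis
  f <- dipole_field(dipole_source(c(0, 0, -20), k, 3), g)
  expect_equal(f$values_hz[11, 11, 11], 2 * k / 20^3)
  # source 20 mm along x: isocenter is equatorial
  f <- dipole_field(dipole_source(c(-20, 0, 0), k, 3), g)
  expect_equal(f$values_hz[11, 11, 11], -k / 20^3)
  # magic angle: direct evaluation at arccos(1/sqrt(3))
  ct <- 1 / sqrt(3)
  d <- 20
  pos <- -c(d * sqrt(1 - ct^2), 0, d * ct)
  gm <- grid3d(c(1, 1, 1), 1, origin_mm = c(0, 0, 0))
  f <- dipole_field(dipole_source(pos, k, 3), gm)
  expect_equal(f$values_hz[1, 1, 1], 0, tolerance = 1e-12)
})

test_that("dipole exclusion zone is flagged invalid and configuration checks hold", {
  g <- grid3d(c(11, 11, 11), 2)
  f <- dipole_field(dipole_source(c(0, 0, 0), 1e4, 5), g)
  ctr <- f$valid_mask[6, 6, 6]
  expect_false(ctr)                      # r = 0 < 5 mm
  expect_false(f$valid_mask[7, 6, 6])    # r = 2 mm
  expect_true(f$valid_mask[6, 6, 9])     # r = 6 mm
  expect_error(dipole_source(c(0, 0, 0), 1, 0), "zero-radius")
})

test_that("lead field is a dipole superposition: degenerate and linear cases", {
  g <- grid3d(c(17, 17, 17), 2)
  p <- c(0, 0, -14)
  # two co-located points with strengths k each == one point with 2k
  lead2 <- lead_source(rbind(p, p), 5e4, 0, 2)
  f2 <- lead_field(lead2, g)
  f1 <- dipole_field(dipole_source(p, 1e5, 2), g)
  expect_equal(f2$values_hz, f1$values_hz)
  expect_equal(f2$valid_mask, f1$valid_mask)
  expect_error(lead_source(matrix(p, 1, 3), 1), "n >= 2")
})

test_that("helical lead field equals brute-force per-voxel summation", {
  g <- grid3d(c(12, 12, 12), 3)
  path <- helical_lead_path(4, 3, 1.5, points_per_turn = 14)[1:20, ]
  src <- lead_source(path, 2e3, 5e3, 2)
  f <- lead_field(src, g)
  pts <- rbind(path, path[nrow(path), ])
  oracle <- brute_dipole_sum(pts, c(rep(2e3, nrow(path)), 5e3), g)
  expect_equal(f$values_hz[f$valid_mask], oracle[f$valid_mask],
               tolerance = 1e-12)
})

test_that("lead path sampling is enforced against the grid", {
  g <- grid3d(c(12, 12, 12), 1)
  path <- helical_lead_path(10, 4, 1, points_per_turn = 8)  # ~8 mm spacing
  expect_error(lead_field(lead_source(path, 1e3), g), "undersampled")
})

test_that("cos^4 displacement law: extremes, zero crossing, time average", {
  m <- motion_pattern(20, 4, baseline_mm = 3)
  expect_equal(lujan_position(0, m), 3 - 20)      # cos(0) = 1
  expect_equal(lujan_position(2, m), 3)           # cos(pi/2) = 0
  expect_equal(lujan_position(4.5, m), lujan_position(0.5, m))  # periodic
  # analytic mean of cos^4 over a period is 3/8, checked by quadrature
  avg <- integrate(function(t) lujan_position(t, m), 0, 4)$value / 4
  expect_equal(avg, 3 - 20 * 3 / 8, tolerance = 1e-8)
  expect_error(motion_pattern(20, 4, exponent = 3), "even")
  expect_error(motion_pattern(-1, 4), ">= 0")
})

test_that("scene field composes sources and translates the scene rigidly", {
  scene <- tiny_implant_scene(NA)
  f <- scene_offresonance(scene, c(0, 0, 0))
  expect_true(all(f$values_hz == 0))
  sph <- sphere_mask(scene$target, c(0, 0, 0), scene$grid)
  expect_equal(f$magnitude[sph][1], 1)
  expect_equal(sort(unique(as.vector(f$magnitude))), c(0.25, 1))

  scene2 <- tiny_implant_scene(85)
  f0 <- scene_offresonance(scene2, c(0, 0, 0))
  fd <- scene_offresonance(scene2, c(4, -4, 8))
  fb <- scene_offresonance(scene2, c(4, -4, 8) - c(4, -4, 8))
  expect_identical(fb$values_hz, f0$values_hz)      # involution
  expect_identical(fb$magnitude, f0$magnitude)
  expect_false(identical(fd$values_hz, f0$values_hz))
  # single dipole scene equals dipole_field plus uniform background
  fsrc <- dipole_field(scene2$sources[[1]], scene2$grid)
  expect_equal(f0$values_hz, fsrc$values_hz)
})

test_that("static acquisition wraps the phase and respects the noise seed", {
  g <- grid3d(c(8, 8, 8), 4)
  scene <- phantom_scene(g, target_sphere(c(0, 0, 0), 6), list())
  acq <- noise_free_acq()
  # zero field -> phase identically 0
  a <- acquire_static(scene, c(0, 0, 0), acq)
  expect_true(all(a$phase_rad == 0))
  # uniform field at the wrap boundary: 1/(2 dTE) -> phase = pi exactly
  scene_b <- phantom_scene(g, target_sphere(c(0, 0, 0), 6), list(),
                           background_field_hz = 1 / (2 * 0.002))
  ab <- acquire_static(scene_b, c(0, 0, 0), acq)
  expect_equal(unique(as.vector(ab$phase_rad)), pi)
  # one full wrap: 1/dTE -> phase = 0
  scene_c <- phantom_scene(g, target_sphere(c(0, 0, 0), 6), list(),
                           background_field_hz = 1 / 0.002)
  ac <- acquire_static(scene_c, c(0, 0, 0), acq)
  expect_equal(max(abs(ac$phase_rad)), 0, tolerance = 1e-9)
  # identical seeds give bit-identical noisy volumes
  acqn <- acquisition_config(noise_sd = 0.05, seed = 11)
  expect_identical(acquire_static(scene, c(0, 0, 0), acqn),
                   acquire_static(scene, c(0, 0, 0), acqn))
  acqn2 <- acquisition_config(noise_sd = 0.05, seed = 12)
  expect_false(identical(acquire_static(scene, c(0, 0, 0), acqn)$phase_rad,
                         acquire_static(scene, c(0, 0, 0), acqn2)$phase_rad))
})

test_that("dynamic acquisition reduces to static for zero-amplitude or uniform fields", {
  scene <- tiny_implant_scene(60, shape = c(16, 16, 16), voxel = 4)
  acq <- acquisition_config(noise_sd = 0.02, seed = 5, n_motion_phases = 8)
  still <- motion_pattern(0, 4, baseline_mm = 0)
  d <- acquire_dynamic(scene, still, acq)
  s <- acquire_static(scene, c(0, 0, 0), acq)
  expect_equal(d$phase_rad, s$phase_rad, tolerance = 1e-12)
  expect_equal(d$magnitude, s$magnitude, tolerance = 1e-12)

  # spatially uniform field: motion changes magnitude but not phase
  g <- grid3d(c(10, 10, 10), 4)
  su <- phantom_scene(g, target_sphere(c(0, 0, 0), 8), list(),
                      background_field_hz = 120)
  du <- acquire_dynamic(su, motion_pattern(16, 4), noise_free_acq())
  stu <- acquire_static(su, c(0, 0, 0), noise_free_acq())
  expect_equal(du$phase_rad, stu$phase_rad, tolerance = 1e-12)
})

test_that("dynamic acquisition equals the brute-force time-loop average", {
  scene <- tiny_implant_scene(70, shape = c(12, 12, 12), voxel = 5)
  acq <- noise_free_acq(n_motion_phases = 8)
  mot <- motion_pattern(20, 4, baseline_mm = 10)
  d <- acquire_dynamic(scene, mot, acq)
  times <- (0:7) / 8 * 4
  sig <- 0
  for (t in times) {
    a <- acquire_static(scene, c(0, 0, lujan_position(t, mot)), acq)
    sig <- sig + as.vector(a$magnitude) * exp(1i * as.vector(a$phase_rad))
  }
  sig <- sig / length(times)
  expect_equal(as.vector(d$phase_rad), Arg(sig), tolerance = 1e-9)
  expect_equal(as.vector(d$magnitude), Mod(sig), tolerance = 1e-9)
})

test_that("dynamic phase converges in the number of motion phases", {
  scene <- tiny_implant_scene(80, shape = c(12, 12, 12), voxel = 4,
                              strength = 3e8)
  mot <- motion_pattern(10, 4, baseline_mm = 5)
  d16 <- acquire_dynamic(scene, mot, noise_free_acq(n_motion_phases = 32))
  d32 <- acquire_dynamic(scene, mot, noise_free_acq(n_motion_phases = 64))
  keep <- d16$magnitude > 0.05 & d32$magnitude > 0.05
  dphi <- wrap_to_pi(d16$phase_rad[keep] - d32$phase_rad[keep])
  # agreement within the phase-noise floor of the default acquisition
  expect_lt(max(abs(dphi)), 0.08)
})

test_that("dipole field is discretely harmonic with second-order convergence", {
  k <- 1e6
  src <- function() dipole_source(c(0, 0, -40), k, 5)
  lap_scale <- function(voxel, shape) {
    g <- grid3d(shape, voxel)
    f <- dipole_field(src(), g)$values_hz
    n <- dim(f)
    lap <- f[2:(n[1] - 1), 2:(n[2] - 1), 2:(n[3] - 1)] * -6 +
      f[1:(n[1] - 2), 2:(n[2] - 1), 2:(n[3] - 1)] +
      f[3:n[1], 2:(n[2] - 1), 2:(n[3] - 1)] +
      f[2:(n[1] - 1), 1:(n[2] - 2), 2:(n[3] - 1)] +
      f[2:(n[1] - 1), 3:n[2], 2:(n[3] - 1)] +
      f[2:(n[1] - 1), 2:(n[2] - 1), 1:(n[3] - 2)] +
      f[2:(n[1] - 1), 2:(n[2] - 1), 3:n[3]]
    # probe a fixed physical box well away from the source (z in [8, 24] mm)
    g2 <- grid3d(shape - 2L, voxel)
    z <- grid_axis_mm(g2, 3)
    sel <- abs(outer(outer(rep(0, shape[1] - 2), rep(0, shape[2] - 2), `+`),
                     z, `+`)) |> (\(a) a >= 8 & a <= 24)()
    max(abs(lap[sel])) / voxel^2
  }
  l2 <- lap_scale(2, c(17L, 17L, 33L))
  l1 <- lap_scale(1, c(33L, 33L, 65L))
  expect_gt(l2 / l1, 2.5)  # ~4 expected for O(h^2)
  expect_lt(l2 / l1, 6)
})
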