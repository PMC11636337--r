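test_that("static averaging is the voxel-wise mean on the mask intersection", {
  g <- grid3d(c(6, 6, 4), 5)
  v <- array(rnorm(prod(g$shape)), g$shape)
  m1 <- make_map(v, g)
  expect_equal(average_static(list(m1))$values_hz, m1$values_hz)  # identity
  m2 <- make_map(-v, g)
  expect_true(all(average_static(list(m1, m2))$values_hz == 0))
  # 7 random maps with random validity: brute-force per-voxel mean
  set.seed(8)
  maps <- lapply(1:7, function(i) {
    make_map(array(rnorm(prod(g$shape)), g$shape), g,
             valid = array(runif(prod(g$shape)) > 0.2, g$shape))
  })
  avg <- average_static(maps)
  expect_identical(avg$valid_mask, Reduce(`&`, lapply(maps, `[[`, "valid_mask")))
  idx <- which(avg$valid_mask)[1:20]
  for (i in idx) {
    expect_equal(avg$values_hz[i],
                 mean(vapply(maps, function(m) m$values_hz[i], numeric(1))))
  }
  g2 <- grid3d(c(6, 6, 4), 4)
  expect_error(average_static(list(m1, make_map(v, g2))), "common grid")
})

test_that("paired voxels honour the triple mask intersection in scan order", {
  g <- grid3d(c(5, 5, 4), 5)
  n <- prod(g$shape)
  set.seed(12)
  ref <- make_map(array(rnorm(n), g$shape), g,
                  valid = array(runif(n) > 0.3, g$shape))
  dyn <- make_map(array(rnorm(n), g$shape), g,
                  valid = array(runif(n) > 0.3, g$shape))
  roi <- array(runif(n) > 0.4, g$shape)
  s <- paired_voxels(ref, dyn, roi)
  sel <- roi & ref$valid_mask & dyn$valid_mask
  expect_identical(length(s$a_hz), sum(sel))          # set-logic oracle
  expect_identical(s$a_hz, ref$values_hz[sel])        # column-major order
  # an all-valid roi of 10 voxels gives exactly 10 pairs
  roi10 <- array(FALSE, g$shape)
  roi10[which(sel)[1:10]] <- TRUE
  expect_identical(paired_voxels(ref, dyn, roi10)$a_hz |> length(), 10L)
  # a fully void roi raises
  deadroi <- array(FALSE, g$shape)
  deadroi[which(!ref$valid_mask)[1]] <- TRUE
  expect_error(paired_voxels(ref, dyn, deadroi), "no valid paired voxels")
})

test_that("Bland-Altman statistics match hand-computed and brute-force values", {
  # identical samples: zero difference and zero spread
  s <- paired_samples(c(1, 2, 3), c(1, 2, 3))
  r <- bland_altman(s)
  expect_equal(r$mean_diff_hz, 0); expect_equal(r$spread_hz, 0)
  # constant offset: mean_diff = c, sd = 0
  r <- bland_altman(paired_samples(c(1, 2, 3), c(1, 2, 3) + 7.5))
  expect_equal(r$mean_diff_hz, 7.5); expect_equal(r$sd_diff_hz, 0)
  # d = {-1, 0, 1} -> sample SD 1 Hz, spread 1.96 Hz
  r <- bland_altman(paired_samples(c(0, 0, 0), c(-1, 0, 1)))
  expect_equal(r$sd_diff_hz, 1); expect_equal(r$spread_hz, 1.96)
  expect_equal(r$loa_hz, c(-1.96, 1.96))
  # brute-force agreement to 1e-12 relative at n = 1e4
  set.seed(99)
  a <- rnorm(1e4, 50, 30); b <- a + rnorm(1e4, 5, 12)
  r <- bland_altman(paired_samples(a, b))
  o <- brute_bland_altman(a, b)
  expect_equal(r$mean_diff_hz, o$mean_diff, tolerance = 1e-12)
  expect_equal(r$sd_diff_hz, o$sd_diff, tolerance = 1e-12)
  expect_equal(r$spread_hz, o$spread, tolerance = 1e-12)
  expect_equal(r$loa_hz, o$loa, tolerance = 1e-12)
  expect_equal(r$mean_of_means_hz, o$mean_of_means, tolerance = 1e-12)
})

test_that("swapping the two samples negates the mean difference only", {
  set.seed(5)
  a <- rnorm(200); b <- rnorm(200)
  r1 <- bland_altman(paired_samples(a, b))
  r2 <- bland_altman(paired_samples(b, a))
  expect_equal(r1$mean_diff_hz, -r2$mean_diff_hz)
  expect_equal(r1$sd_diff_hz, r2$sd_diff_hz)
  expect_equal(r1$mean_of_means_hz, r2$mean_of_means_hz)
})

test_that("central-fraction intervals nest and a single pair flags the SD", {
  set.seed(21)
  a <- rnorm(500); b <- a + rnorm(500)
  cb <- bland_altman(paired_samples(a, b), c(0.5, 0.95))$central_bounds
  expect_true(cb$diff_lo_hz[1] >= cb$diff_lo_hz[2])
  expect_true(cb$diff_hi_hz[1] <= cb$diff_hi_hz[2])
  expect_true(cb$mean_lo_hz[1] >= cb$mean_lo_hz[2])
  expect_true(cb$mean_hi_hz[1] <= cb$mean_hi_hz[2])
  r1 <- bland_altman(paired_samples(3, 4))
  expect_false(r1$sd_defined)
  expect_true(is.na(r1$sd_diff_hz))
  expect_equal(r1$mean_diff_hz, 1)
})

test_that("shell profiles report every band and preserve the pair partition", {
  g <- grid3d(c(13, 13, 9), 2)
  void <- array(FALSE, g$shape); void[7, 7, 5] <- TRUE
  ss <- distance_shells(void, n_bands = 6, band_width_mm = 2, grid = g)
  v <- array(rnorm(prod(g$shape)), g$shape)
  ref <- make_map(v, g, valid = !void)
  # identical maps -> all shell means and SDs zero
  prof <- shell_profile(ref, ref, ss)
  df <- as.data.frame(prof)
  expect_identical(nrow(df), 6L)
  nz <- df$n_pairs > 0
  expect_true(all(df$mean_diff_hz[nz] == 0))
  expect_true(all(df$sd_diff_hz[nz] == 0))
  # empty bands are explicit records, not dropped (band [0,2) has no voxel
  # centers closer than 2 mm to the void center)
  expect_identical(df$n_pairs[1], 0L)
  expect_true(is.na(df$mean_diff_hz[1]))
  # per-shell n sums to the n of the union region
  dyn <- make_map(v + 1, g, valid = !void)
  union_roi <- Reduce(`|`, ss$shells)
  expect_identical(sum(as.data.frame(shell_profile(ref, dyn, ss))$n_pairs),
                   length(paired_voxels(ref, dyn, union_roi)$a_hz))
})

test_that("a difference field decaying with distance yields non-increasing shell means", {
  g <- grid3d(c(17, 17, 13), 2)
  void <- array(FALSE, g$shape); void[9, 9, 7] <- TRUE
  ss <- distance_shells(void, n_bands = 7, band_width_mm = 2, grid = g)
  ref <- make_map(array(0, g$shape), g, valid = !void)
  # constructed monotone field: difference = 100 / (1 + distance)
  dyn <- make_map(100 / (1 + ss$distance_mm), g, valid = !void)
  df <- as.data.frame(shell_profile(ref, dyn, ss))
  means <- df$mean_diff_hz[df$n_pairs > 0]
  expect_true(all(diff(means) <= 1e-12))
})
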