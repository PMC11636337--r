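# Independent brute-force oracles and small fixture builders.

# triple-loop dipole superposition (z = main-field axis)
brute_dipole_sum <- function(pts, strength, grid) {
  ax <- grid_axis_mm(grid, 1); ay <- grid_axis_mm(grid, 2)
  az <- grid_axis_mm(grid, 3)
  out <- array(0, grid$shape)
  for (i in seq_along(ax)) for (j in seq_along(ay)) for (k in seq_along(az)) {
    v <- 0
    for (p in seq_len(nrow(pts))) {
      d <- c(ax[i], ay[j], az[k]) - pts[p, ]
      r <- sqrt(sum(d^2))
      ct <- d[3] / r
      v <- v + strength[p] * (3 * ct^2 - 1) / r^3
    }
    out[i, j, k] <- v
  }
  out
}

# classic sequential 1D phase unwrapping (cumulative wrap correction)
brute_unwrap_1d <- function(wrapped) {
  out <- wrapped
  for (i in seq_along(wrapped)[-1]) {
    out[i] <- wrapped[i] +
      2 * pi * round((out[i - 1] - wrapped[i]) / (2 * pi))
  }
  out
}

# all-pairs nearest-void distance in mm
brute_edt_mm <- function(void_mask, grid) {
  ax <- grid_axis_mm(grid, 1); ay <- grid_axis_mm(grid, 2)
  az <- grid_axis_mm(grid, 3)
  idx <- which(void_mask, arr.ind = TRUE)
  vp <- cbind(ax[idx[, 1]], ay[idx[, 2]], az[idx[, 3]])
  out <- array(NA_real_, grid$shape)
  for (i in seq_along(ax)) for (j in seq_along(ay)) for (k in seq_along(az)) {
    d2 <- (vp[, 1] - ax[i])^2 + (vp[, 2] - ay[j])^2 + (vp[, 3] - az[k])^2
    out[i, j, k] <- sqrt(min(d2))
  }
  out
}

# textbook Bland-Altman with explicit loops
brute_bland_altman <- function(a, b) {
  n <- length(a)
  d <- numeric(n); m <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- b[i] - a[i]
    m[i] <- (a[i] + b[i]) / 2
  }
  md <- sum(d) / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (d[i] - md)^2
  sdd <- sqrt(ss / (n - 1))
  list(mean_diff = md, sd_diff = sdd, spread = 1.96 * sdd,
       loa = c(md - 1.96 * sdd, md + 1.96 * sdd),
       mean_of_means = sum(m) / n)
}

# small implant scene for unwrap/pipeline unit tests
tiny_implant_scene <- function(distance_mm = 85, shape = c(32, 32, 24),
                               voxel = 4, strength = 1.1e9) {
  grid <- grid3d(shape, voxel)
  u <- c(1, 0, 1) / sqrt(2)
  src <- if (is.na(distance_mm)) list() else
    list(dipole_source(distance_mm * u, strength, 15))
  phantom_scene(grid, target_sphere(c(0, 0, 0), 15), src)
}

noise_free_acq <- function(...) {
  acquisition_config(noise_sd = 0, ...)
}

# synthetic offresonance_map with prescribed values/wraps
make_map <- function(values_hz, grid, valid = NULL, wraps = NULL,
                     delta_te_s = 0.002) {
  if (is.null(valid)) valid <- array(TRUE, grid$shape)
  offresonance_map(values_hz, valid, grid, wrap_count = wraps,
                   delta_te_s = delta_te_s)
}
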