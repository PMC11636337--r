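#' Paired voxel samples (static reference vs dynamic comparison)
#'
#' @param a_hz Reference (static) values in Hz.
#' @param b_hz Comparison (dynamic) values in Hz; same length as `a_hz`.
#' @param label Configuration or shell identifier.
#' @return An object of class `paired_samples`.
#' @export
paired_samples <- function(a_hz, b_hz, label = "") {
  a_hz <- as.numeric(a_hz); b_hz <- as.numeric(b_hz)
  if (length(a_hz) != length(b_hz) || length(a_hz) < 1)
    stop("a_hz and b_hz must have equal length >= 1")
  if (any(!is.finite(a_hz)) || any(!is.finite(b_hz)))
    stop("paired samples must be finite (exclude void/invalid voxels first)")
  structure(list(a_hz = a_hz, b_hz = b_hz, label = as.character(label)),
            class = "paired_samples")
}

#' Concatenate paired samples (group-wise pooling)
#'
#' Pools per-position pair lists into one group-wise sample.
#'
#' @param samples List of [paired_samples()].
#' @param label Label for the pooled sample.
#' @return A [paired_samples()].
#' @export
pool_pairs <- function(samples, label = "pooled") {
  stopifnot(length(samples) >= 1)
  paired_samples(unlist(lapply(samples, `[[`, "a_hz")),
                 unlist(lapply(samples, `[[`, "b_hz")), label)
}

#' Average static off-resonance maps
#'
#' Voxel-wise mean over maps where valid in all inputs; the validity mask of
#' the result is the intersection of the input masks.
#'
#' @param maps List of [offresonance_map()] on a common grid (>= 1).
#' @return An [offresonance_map()] (no `wrap_count`: the average is a derived
#'   map, not an unwrapping).
#' @export
average_static <- function(maps) {
  stopifnot(length(maps) >= 1)
  grid <- maps[[1]]$grid
  for (m in maps) {
    stopifnot(inherits(m, "offresonance_map"))
    if (!same_grid(grid, m$grid)) stop("maps must share a common grid")
  }
  valid <- Reduce(`&`, lapply(maps, `[[`, "valid_mask"))
  values <- Reduce(`+`, lapply(maps, `[[`, "values_hz")) / length(maps)
  values[!valid] <- 0
  offresonance_map(values, valid, grid,
                   delta_te_s = maps[[1]]$delta_te_s)
}

#' Collect paired voxels from two maps inside a region
#'
#' Pairs are collected over `roi_mask` intersected with the valid masks of
#' both maps (voxels inside signal voids are excluded), in deterministic
#' column-major scan order.
#'
#' @param reference Static reference [offresonance_map()].
#' @param dynamic Dynamic comparison [offresonance_map()].
#' @param roi_mask Logical region mask on the common grid.
#' @param label Label passed to the result.
#' @return A [paired_samples()].
#' @export
paired_voxels <- function(reference, dynamic, roi_mask, label = "") {
  stopifnot(inherits(reference, "offresonance_map"),
            inherits(dynamic, "offresonance_map"))
  if (!same_grid(reference$grid, dynamic$grid))
    stop("maps must share a common grid")
  check_mask(roi_mask, reference$grid, "roi_mask")
  sel <- roi_mask & reference$valid_mask & dynamic$valid_mask
  if (!any(sel))
    stop("no valid paired voxels: region does not overlap both valid masks")
  paired_samples(reference$values_hz[sel], dynamic$values_hz[sel], label)
}

#' Bland-Altman agreement statistics
#'
#' For paired samples (a = static reference, b = dynamic comparison) computes
#' differences d = b - a and means m = (a + b)/2, the mean difference, the
#' sample SD of the differences (n - 1 denominator), the spread 1.96 * SD,
#' the limits of agreement, and for each requested central fraction f the
#' symmetric empirical-quantile interval [Q_(1-f)/2, Q_(1+f)/2] on both the
#' mean axis and the difference axis (the "smallest region containing f of
#' the data" convention used for plotting). Quantiles use linear
#' interpolation between order statistics.
#'
#' @param s A [paired_samples()].
#' @param central_fractions Fractions for central-interval bounds.
#' @return An object of class `agreement_result` with fields `mean_diff_hz`,
#'   `sd_diff_hz`, `spread_hz`, `loa_hz`, `mean_of_means_hz`, `n_pairs`,
#'   `central_bounds` (data frame), `sd_defined`, `label`. With a single
#'   pair the SD (and everything derived from it) is flagged undefined.
#' @export
bland_altman <- function(s, central_fractions = c(0.5, 0.95)) {
  stopifnot(inherits(s, "paired_samples"))
  d <- s$b_hz - s$a_hz
  m <- (s$a_hz + s$b_hz) / 2
  n <- length(d)
  mean_diff <- mean(d)
  sd_defined <- n >= 2
  sd_diff <- if (sd_defined) sd(d) else NA_real_
  spread <- 1.96 * sd_diff
  cb <- do.call(rbind, lapply(central_fractions, function(f) {
    p <- c((1 - f) / 2, (1 + f) / 2)
    qm <- quantile(m, p, names = FALSE, type = 7)
    qd <- quantile(d, p, names = FALSE, type = 7)
    data.frame(fraction = f, mean_lo_hz = qm[1], mean_hi_hz = qm[2],
               diff_lo_hz = qd[1], diff_hi_hz = qd[2])
  }))
  structure(list(mean_diff_hz = mean_diff, sd_diff_hz = sd_diff,
                 spread_hz = spread,
                 loa_hz = c(mean_diff - spread, mean_diff + spread),
                 mean_of_means_hz = mean(m), n_pairs = n,
                 central_bounds = cb, sd_defined = sd_defined,
                 diff_sign = "dynamic - static", label = s$label),
            class = "agreement_result")
}

empty_agreement <- function(label) {
  structure(list(mean_diff_hz = NA_real_, sd_diff_hz = NA_real_,
                 spread_hz = NA_real_, loa_hz = c(NA_real_, NA_real_),
                 mean_of_means_hz = NA_real_, n_pairs = 0L,
                 central_bounds = NULL, sd_defined = FALSE,
                 diff_sign = "dynamic - static", label = label),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> %s: n=%d, mean diff %.2f Hz, 1.96*SD %.2f Hz\n",
    x$label, x$n_pairs, x$mean_diff_hz, x$spread_hz))
  invisible(x)
}

#' @export
as.data.frame.agreement_result <- function(x, ...) {
  df <- data.frame(label = x$label, n_pairs = x$n_pairs,
                   mean_diff_hz = x$mean_diff_hz, sd_diff_hz = x$sd_diff_hz,
                   spread_hz = x$spread_hz,
                   loa_lo_hz = x$loa_hz[1], loa_hi_hz = x$loa_hz[2],
                   mean_of_means_hz = x$mean_of_means_hz,
                   stringsAsFactors = FALSE)
  if (!is.null(x$central_bounds)) {
    for (i in seq_len(nrow(x$central_bounds))) {
      f <- x$central_bounds$fraction[i]
      tag <- paste0("central", round(100 * f))
      df[[paste0(tag, "_diff_lo_hz")]] <- x$central_bounds$diff_lo_hz[i]
      df[[paste0(tag, "_diff_hi_hz")]] <- x$central_bounds$diff_hi_hz[i]
      df[[paste0(tag, "_mean_lo_hz")]] <- x$central_bounds$mean_lo_hz[i]
      df[[paste0(tag, "_mean_hi_hz")]] <- x$central_bounds$mean_hi_hz[i]
    }
  }
  df
}

#' Bland-Altman plot of an agreement analysis
#'
#' @param x A [paired_samples()].
#' @param result Optional precomputed [bland_altman()] result.
#' @param ... Passed to [plot()].
#' @return Invisibly, the [bland_altman()] result.
#' @export
plot.paired_samples <- function(x, result = NULL, ...) {
  if (is.null(result)) result <- bland_altman(x)
  d <- x$b_hz - x$a_hz
  m <- (x$a_hz + x$b_hz) / 2
  graphics::plot(m, d, pch = 16, cex = 0.4, col = "#00000044",
       xlab = "mean of static and dynamic (Hz)",
       ylab = "dynamic - static (Hz)",
       main = x$label, ...)
  graphics::abline(h = result$mean_diff_hz, col = "blue")
  graphics::abline(h = result$loa_hz, col = "red", lty = 2)
  invisible(result)
}

#' Per-shell agreement profile around a signal void
#'
#' One [bland_altman()] result per distance shell, ordered by distance.
#' Shells with no valid paired voxels yield an explicit empty record
#' (`n_pairs = 0`), never a silently dropped row.
#'
#' @param reference Static (averaged) [offresonance_map()].
#' @param dynamic Dynamic [offresonance_map()].
#' @param shells A [shell_set()][distance_shells()].
#' @param central_fractions Passed to [bland_altman()].
#' @return An object of class `shell_profile`: list of `agreement_result`,
#'   one per band; see [as.data.frame.shell_profile()].
#' @export
shell_profile <- function(reference, dynamic, shells,
                          central_fractions = c(0.5, 0.95)) {
  stopifnot(inherits(shells, "shell_set"))
  res <- lapply(seq_along(shells$shells), function(i) {
    lab <- sprintf("%g-%g mm", shells$band_edges_mm[i, 1],
                   shells$band_edges_mm[i, 2])
    sel <- shells$shells[[i]] & reference$valid_mask & dynamic$valid_mask
    if (!any(sel)) return(empty_agreement(lab))
    bland_altman(paired_samples(reference$values_hz[sel],
                                dynamic$values_hz[sel], lab),
                 central_fractions)
  })
  structure(list(results = res, band_edges_mm = shells$band_edges_mm),
            class = "shell_profile")
}

#' @export
as.data.frame.shell_profile <- function(x, ...) {
  base <- data.frame(band_lo_mm = x$band_edges_mm[, 1],
                     band_hi_mm = x$band_edges_mm[, 2])
  stats <- do.call(rbind, lapply(x$results, function(r) {
    data.frame(label = r$label, n_pairs = r$n_pairs,
               mean_diff_hz = r$mean_diff_hz, sd_diff_hz = r$sd_diff_hz,
               spread_hz = r$spread_hz, stringsAsFactors = FALSE)
  }))
  cbind(base, stats)
}
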