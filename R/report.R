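#' Readout-bandwidth configuration
#'
#' The frequency-encoding gradient strength that translates off-resonance
#' into geometric displacement along the readout axis. The default 450 Hz/mm
#' is a typical clinical readout bandwidth.
#'
#' @param readout_bandwidth_hz_per_mm Bandwidth in Hz per mm, > 0.
#' @return An object of class `bandwidth_config`.
#' @export
bandwidth_config <- function(readout_bandwidth_hz_per_mm = 450) {
  if (!is.finite(readout_bandwidth_hz_per_mm) ||
      readout_bandwidth_hz_per_mm <= 0)
    stop("readout_bandwidth_hz_per_mm must be > 0")
  structure(list(readout_bandwidth_hz_per_mm =
                   as.numeric(readout_bandwidth_hz_per_mm)),
            class = "bandwidth_config")
}

#' Convert an off-resonance offset to geometric distortion
#'
#' `offset / readout_bandwidth`: a 450 Hz/mm readout displaces a 450 Hz
#' off-resonant voxel by 1 mm. Exact (linear) at full precision; reports
#' round to 2 decimals via [report_mm()].
#'
#' @param offset_hz Off-resonance offset(s) in Hz (vectorised).
#' @param bw A [bandwidth_config()].
#' @return Displacement(s) in mm, full precision.
#' @examples
#' hz_to_mm(161)            # 0.3578 mm
#' report_mm(hz_to_mm(161)) # 0.36
#' @export
hz_to_mm <- function(offset_hz, bw = bandwidth_config()) {
  stopifnot(inherits(bw, "bandwidth_config"))
  offset_hz / bw$readout_bandwidth_hz_per_mm
}

#' Round a distortion to report precision
#'
#' Two decimals, round-half-even (the default IEEE behaviour of [round()]).
#'
#' @param mm Distortion(s) in mm.
#' @return `mm` rounded to 2 decimals.
#' @export
report_mm <- function(mm) round(mm, 2)

#' Decide MRgRT eligibility from wraps in the target region
#'
#' Applies the conservative qualitative rule: where phase wraps are present
#' in the target area the B0-map uncertainty is large enough that the implied
#' distortion is likely clinically relevant, so the configuration is
#' `ineligible`; a target that is entirely signal void is `indeterminate`;
#' otherwise `eligible`. The agreement spread is converted to mm and reported
#' as supporting evidence, not thresholded (no mm threshold is defined).
#'
#' @param map Unwrapped [offresonance_map()] (with `wrap_count`).
#' @param target_mask Logical target-region mask on the map's grid.
#' @param agreement An [agreement_result][bland_altman()] for the target.
#' @param bw A [bandwidth_config()].
#' @param label Configuration label.
#' @param provenance Optional named list (seed, config hash, ...) stored
#'   verbatim in the report.
#' @return An object of class `eligibility_report`.
#' @export
decide_eligibility <- function(map, target_mask, agreement,
                               bw = bandwidth_config(), label = "",
                               provenance = list()) {
  stopifnot(inherits(agreement, "agreement_result"))
  wraps <- wraps_in_region(map, target_mask)
  verdict <- if (is.na(wraps)) "indeterminate"
             else if (wraps >= 1L) "ineligible" else "eligible"
  structure(list(
    label = as.character(label),
    wraps_in_target = wraps,
    verdict = verdict,
    target_agreement = agreement,
    spread_hz = agreement$spread_hz,
    spread_mm = report_mm(hz_to_mm(agreement$spread_hz, bw)),
    mean_diff_hz = agreement$mean_diff_hz,
    mean_offset_hz_range = NULL,
    readout_bandwidth_hz_per_mm = bw$readout_bandwidth_hz_per_mm,
    provenance = c(provenance,
                   list(package_version = as.character(packageVersion("b0gate"))))),
    class = "eligibility_report")
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat(sprintf("<eligibility_report> %s\n", x$label))
  cat(sprintf("  wraps in target : %s\n",
              ifelse(is.na(x$wraps_in_target), "indeterminate",
                     x$wraps_in_target)))
  cat(sprintf("  verdict         : %s\n", x$verdict))
  cat(sprintf("  mean diff       : %.2f Hz\n", x$mean_diff_hz))
  cat(sprintf("  spread (1.96SD) : %.2f Hz = %.2f mm at %g Hz/mm\n",
              x$spread_hz, x$spread_mm, x$readout_bandwidth_hz_per_mm))
  invisible(x)
}

report_to_list <- function(x) {
  list(label = x$label,
       wraps_in_target = if (is.na(x$wraps_in_target)) "indeterminate"
                         else x$wraps_in_target,
       verdict = x$verdict,
       mean_diff_hz = x$mean_diff_hz,
       spread_hz = x$spread_hz,
       spread_mm = x$spread_mm,
       mean_offset_hz_range = x$mean_offset_hz_range,
       readout_bandwidth_hz_per_mm = x$readout_bandwidth_hz_per_mm,
       n_pairs = x$target_agreement$n_pairs,
       diff_sign = x$target_agreement$diff_sign,
       provenance = x$provenance)
}

#' Write an eligibility report as JSON
#'
#' @param report An [eligibility_report][decide_eligibility()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "eligibility_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an eligibility report written by [write_report_json()]
#'
#' @param path JSON file path.
#' @return A plain list mirroring the JSON structure.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
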