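#' Synthetic ECG trace with sum-of-Gaussians PQRST morphology
#'
#' A clean single-lead ECG: each beat is a fixed set of Gaussian deflections
#' (P, Q, R, S, T) whose offsets and widths scale with the RR interval, so
#' the morphology stays well-formed across the physiological heart-rate
#' range. The R peak (amplitude 1 mV) dominates. The first R peak falls at
#' t = 0.
#'
#' @param hr_bpm Heart rate in beats per minute, within 30-220.
#' @param duration_s Trace duration in seconds.
#' @param fs Sampling rate in Hz, >= 200.
#' @return An object of class `ecg_trace`: `samples` (mV),
#'   `sampling_rate_hz`, `true_hr_bpm`.
#' @examples
#' tr <- synth_ecg(70, 4)
#' detect_hr(tr)$bpm
#' @export
synth_ecg <- function(hr_bpm, duration_s = 4, fs = 500) {
  if (!is.finite(hr_bpm) || hr_bpm < 30 || hr_bpm > 220)
    stop("hr_bpm must be within 30-220")
  if (fs < 200) stop("sampling rate must be >= 200 Hz")
  if (duration_s <= 0) stop("duration_s must be > 0")
  rr <- 60 / hr_bpm
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  # wave offsets/widths as fractions of RR, amplitudes in mV
  off <- c(p = -0.22, q = -0.03, r = 0, s = 0.03, t = 0.35) * rr
  sig <- c(p = 0.04, q = 0.01, r = 0.018, s = 0.012, t = 0.06) * rr
  amp <- c(p = 0.12, q = -0.12, r = 1.0, s = -0.18, t = 0.25)
  x <- numeric(length(t))
  for (b in seq(-1, ceiling(duration_s / rr))) {
    tr <- b * rr
    for (w in seq_along(amp)) {
      # R deflections only for beats inside the window (first at t = 0);
      # P/T tails of neighbouring beats may spill across the edges
      if (names(amp)[w] == "r" && (tr < 0 || tr >= duration_s)) next
      x <- x + amp[w] * exp(-(t - tr - off[w])^2 / (2 * sig[w]^2))
    }
  }
  structure(list(samples = x, sampling_rate_hz = fs,
                 true_hr_bpm = hr_bpm),
            class = "ecg_trace")
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat(sprintf("<ecg_trace> %.1f s at %g Hz, true HR %s bpm\n",
              length(x$samples) / x$sampling_rate_hz, x$sampling_rate_hz,
              ifelse(is.null(x$true_hr_bpm), "unknown", x$true_hr_bpm)))
  invisible(x)
}

#' @export
plot.ecg_trace <- function(x, ...) {
  t <- (seq_along(x$samples) - 1) / x$sampling_rate_hz
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)",
                 ylab = "ECG (mV)", ...)
  invisible(x)
}

#' Gradient-switching ECG artifact model
#'
#' MR gradient activity is modelled as a trapezoidal waveform repeated every
#' `repetition_interval_s`; the induced ECG artifact is its time derivative
#' (induction scales with dG/dt), i.e. bipolar pulses of width `ramp_time_s`
#' at each ramp, normalised to `amplitude_mv` and scaled by `gain`. Sequence
#' presets mirror which acquisitions leave the ECG readable: slow 3D planning
#' sequences (low gain, sparse ramps) versus fast multi-plane cine monitoring
#' (high gain, dense ramps).
#'
#' @param repetition_interval_s Trapezoid repetition interval, > 0.
#' @param ramp_time_s Gradient ramp time (artifact pulse width).
#' @param amplitude_mv Artifact pulse amplitude at gain 1.
#' @param gain Scalar multiplier (>= 0) for a sequence/position combination.
#' @return An object of class `artifact_model`.
#' @export
artifact_model <- function(repetition_interval_s, ramp_time_s = 0.004,
                           amplitude_mv = 1, gain = 1) {
  if (!is.finite(repetition_interval_s) || repetition_interval_s <= 0)
    stop("repetition_interval_s must be > 0")
  if (ramp_time_s <= 0 || ramp_time_s >= repetition_interval_s / 2)
    stop("ramp_time_s must be in (0, repetition_interval_s/2)")
  if (gain < 0) stop("gain must be >= 0")
  structure(list(repetition_interval_s = repetition_interval_s,
                 ramp_time_s = ramp_time_s,
                 amplitude_mv = amplitude_mv, gain = gain),
            class = "artifact_model")
}

#' Sequence presets for the artifact model
#'
#' `"cine_2plane"`: fast interleaved 2D cine monitoring - dense gradient
#' ramps, strong induction. `"t2_3d"`: slow 3D turbo-spin-echo planning
#' sequence - sparse ramps, weak induction (ECG stays readable).
#'
#' @param preset Preset name.
#' @param gain Optional gain override.
#' @return An [artifact_model()].
#' @export
artifact_preset <- function(preset = c("cine_2plane", "t2_3d"), gain = NULL) {
  preset <- match.arg(preset)
  m <- switch(preset,
    cine_2plane = artifact_model(0.1, 0.004, 1, 4),
    t2_3d = artifact_model(0.8, 0.006, 1, 0.3))
  if (!is.null(gain)) m$gain <- gain
  m
}

artifact_samples <- function(model, n, fs) {
  t <- (seq_len(n) - 1) / fs
  u <- t %% model$repetition_interval_s
  # +pulse on the up-ramp (start of cycle), -pulse on the down-ramp
  # (half cycle later); derivative of a symmetric trapezoid
  x <- numeric(n)
  x[u < model$ramp_time_s] <- 1
  half <- model$repetition_interval_s / 2
  x[u >= half & u < half + model$ramp_time_s] <- -1
  model$gain * model$amplitude_mv * x
}

#' Add MR gradient artifact to an ECG trace
#'
#' `output = trace + gain * pulse_train` sampled on the trace's time grid;
#' the true heart rate is preserved in the metadata. Linear in the gain:
#' injecting gains g1 then g2 equals one injection at g1 + g2.
#'
#' @param trace An [ecg_trace][synth_ecg()].
#' @param model An [artifact_model()].
#' @return An `ecg_trace` with the artifact added.
#' @export
inject_artifact <- function(trace, model) {
  stopifnot(inherits(trace, "ecg_trace"), inherits(model, "artifact_model"))
  trace$samples <- trace$samples +
    artifact_samples(model, length(trace$samples), trace$sampling_rate_hz)
  trace
}

#' Automatic heart-rate detection with an adaptive threshold
#'
#' Peak detection emulating a bedside monitor: candidate peaks are local
#' maxima above an adaptive threshold (a fraction of the rolling signal
#' maximum over a 1 s window), thinned with a 250 ms refractory period. The
#' heart rate is 60 / median(RR). The result is flagged unreliable when
#' fewer than 2 peaks are found or when the RR dispersion (SD/median)
#' exceeds 15 % - the failure modes a monitor reports as "heart rate could
#' not be determined".
#'
#' @param trace An [ecg_trace][synth_ecg()], at least 2 s long.
#' @param threshold_fraction Fraction of the rolling maximum.
#' @param refractory_s Minimum peak spacing in seconds.
#' @return List with `bpm` (NA when < 2 peaks), `reliable` (logical),
#'   `n_peaks`, and the peak times `peaks_s`.
#' @export
detect_hr <- function(trace, threshold_fraction = 0.6, refractory_s = 0.25) {
  stopifnot(inherits(trace, "ecg_trace"))
  x <- trace$samples
  fs <- trace$sampling_rate_hz
  n <- length(x)
  if (n / fs < 2) stop("trace must be at least 2 s long")

  # rolling maximum over a 1 s centered window
  w <- as.integer(fs / 2)
  rmax <- vapply(seq_len(n), function(i) {
    max(x[max(1, i - w):min(n, i + w)])
  }, numeric(1))
  thr <- threshold_fraction * rmax

  cand <- which(x >= thr &
                  x >= c(-Inf, x[-n]) &
                  x > c(x[-1], -Inf))
  # refractory thinning in time order
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    if ((i - last) / fs >= refractory_s) {
      peaks <- c(peaks, i)
      last <- i
    }
  }

  if (length(peaks) < 2) {
    return(list(bpm = NA_real_, reliable = FALSE, n_peaks = length(peaks),
                peaks_s = (peaks - 1) / fs))
  }
  rr <- diff(peaks) / fs
  bpm <- 60 / median(rr)
  dispersion <- if (length(rr) >= 2) sd(rr) / median(rr) else 0
  list(bpm = bpm, reliable = dispersion <= 0.15, n_peaks = length(peaks),
       peaks_s = (peaks - 1) / fs)
}
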