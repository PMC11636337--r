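---
title: "B0-mapping based eligibility screening near cardiac implants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{B0-mapping based eligibility screening near cardiac implants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b0gate)
```

## The problem

Patients with a cardiac implantable electronic device (CIED) are usually
excluded from MR-guided radiotherapy (MRgRT). For thoracic targets the
blocking question is geometric fidelity: the metallic generator and its leads
perturb the main magnetic field (B0), and an off-resonance of $\Delta f$ Hz
displaces signal along the readout direction by $\Delta f / \mathrm{BW}$ mm
at readout bandwidth $\mathrm{BW}$ (450 Hz/mm is typical). A dual-echo
B0-map measures $\Delta f$ per voxel, but it arrives phase-wrapped and, for a
moving thoracic target, is acquired under respiration. `b0gate` implements
the full screening chain as testable code: simulate an implant-perturbed
phantom under cos$^4$ motion, acquire wrapped static and dynamic (free
breathing) phase maps, unwrap them with a quality-guided region-growing
algorithm, quantify static-vs-dynamic agreement with Bland–Altman
statistics (per target position and per distance shell around a lead's
signal void), convert Hz to mm, and apply a conservative eligibility rule:
**wraps in the target area mean the distortion is too uncertain to trust, so
the configuration is ineligible**. A companion module reproduces the MR
gradient-induced ECG distortions that make pulse oximetry indispensable for
in-bore monitoring.

Because no deposited datasets exist for this procedure, the simulator is a
first-class, tested component; all quantitative claims of the package are
about what the simulated pipeline computes.

## Scene and field model

The phantom scene lives on a regular grid (`grid3d`) in mm, right-handed,
with the main field along z and the machine isocenter at the origin (default
128×128×64 voxels at 2 mm, isocenter-centered). It contains a water-filled
target sphere (default radius 15 mm, relative magnitude 1) in a
signal-bearing background (relative magnitude 0.25), and perturbing sources:

* an **implant** as a magnetic point dipole aligned with B0,
  $\Delta f(\mathbf r) = k\,(3\cos^2\theta - 1)/r^3$, invalid (signal void)
  inside an exclusion radius (default 15 mm). This closed form is a physics
  stand-in: the real procedure measures the implant's field rather than
  modelling it, and it gives exact oracles (on-axis $2k/d^3$, equatorial
  $-k/d^3$, zero at the magic angle) for testing.
* a **lead** as a dense chain of weak dipoles along a helix wrapped around a
  cylindrical insert, plus one stronger dipole at the final point — leads
  perturb the field much less and much more locally than the generator, with
  the largest effect near the tip.

The default implant strength, $k = 1.1\times10^9$ Hz·mm³, is calibrated so
that the far setup (implant 175 mm from isocenter, oblique x+z direction)
produces target-region offsets of order 100 Hz; the same $k$ at 85 mm then
spans the target with upwards of 1.5 kHz, several wraps at the default
echo spacing — matching the qualitative ordering reported for measured
setups (roughly −140…−50 Hz far away, −410…+410 Hz and multiple wraps close
in).

**Rigid motion.** A displacement translates the whole scene — target *and*
sources — as a thoracic tumour and an implanted device move together under
respiration. This is a deliberate modelling choice: if only the target
magnitude moved, the field at every voxel would be constant over the
breathing cycle and a complex-average dynamic acquisition would show no
motion effect at all on phase. With rigid motion, the dynamic phase is
biased exactly where the field varies along the motion path, which is the
effect the screening procedure probes, and it grows deterministically as the
implant approaches the target.

## Motion

Displacement follows the classic respiratory law
$z(t) = z_0 - b\,\cos^{2n}(\pi t/\tau + \phi)$ with peak-to-peak amplitude
$b$, period $\tau$ and even exponent $2n$ (default 4). Defaults: $b=20$ mm,
$\tau=4$ s (15 breaths/min), superior–inferior axis. The pipeline
configurations set $z_0 = b/2$ so the excursion spans −10…+10 mm, the same
range as the static position series. Cardiorespiratory motion for lead
setups adds a cardiac cos⁴ component; its parameters are nowhere published
for this procedure, so the package default (2 mm peak-to-peak, 1.0 s,
anterior–posterior) is a config-exposed choice of physiologically plausible
scale, not an inferred value. Multiple patterns sum; the analytic time
average of the cos⁴ law over a cycle, $z_0 - 3b/8$, is used as a test
oracle.

## Acquisition model

The dual-echo phase difference is $\phi = 2\pi\,\Delta f\,\Delta TE$,
wrapped to the half-open interval $(-\pi, \pi]$. The echo spacing is not
published for this procedure; the package default $\Delta TE = 2$ ms gives
an unambiguous range of ±250 Hz per wrap, which is what makes offsets of
several hundred Hz wrap multiple times, as reported. Complex Gaussian noise
(default SD 0.02 of unit magnitude per channel) is added to the complex
signal before phase and magnitude are taken.

Two effects shape the magnitude:

* **Intravoxel dephasing.** A field that varies across a voxel dephases the
  spins within it; with a linear variation the attenuation is
  $\prod_{\text{axes}} |\mathrm{sinc}(\pi\,\Delta TE\,g_a)|$ with $g_a$ the
  per-voxel field step along axis $a$. This creates the familiar signal-void
  shell around metal, and it is the reason magnitude works as an unwrapping
  quality map: exactly the voxels whose phase is unreliable are dark. It
  also keeps the region-growing front out of the aliased shell (see below).
* **Motion averaging.** The dynamic acquisition is modelled as the
  time-average of the complex signal over `n_motion_phases` uniformly spaced
  times across the least common period of the motion patterns (default 16;
  not a k-space simulation). Motion therefore attenuates magnitude where
  the object moves and biases phase where the field changes over the cycle.
  Noise is added once, to the averaged signal, so a zero-amplitude dynamic
  acquisition is identical to the static one at the same seed.

All randomness flows from one integer seed; identical seeds give
bit-identical volumes.

## Phase unwrapping

`region_growing_unwrap` removes wraps with a quality-guided region-growing
scheme driven by both maps: voxels below `void_threshold` × max(magnitude)
(default 0.1) are excluded as signal void; growth starts at the
highest-magnitude voxel (ties broken by linear index, so the result is fully
deterministic) and maintains a priority front ordered by magnitude. Each
popped voxel receives its wrapped phase plus the $2\pi k$ closest to the
mean of its already-unwrapped 6-neighbours. Disconnected valid components
are unwrapped independently, each referenced to zero wraps at its own seed —
no information crosses a signal void. On noise-free fields whose
per-neighbour steps stay below $\pi$, recovery is exact up to one global
$2\pi m$ per component (asserted in the tests); the unwrapped-minus-wrapped
difference is an exact $2\pi$ multiple by construction.

Because each map fixes its global branch at its own seed, the pipeline
re-references every unwrapped map before differencing
(`rereference_branch`): the modal wrap count over the valid volume is
shifted to zero, the analogue of referencing a B0-map to the scanner centre
frequency. Without this step, difference maps between independently
unwrapped acquisitions would carry arbitrary multiples of
$1/\Delta TE = 500$ Hz.

The eligibility rule consumes `wraps_in_region`: the number of distinct
wrap counts among the valid voxels of the target area minus one. A target
that is entirely void yields an explicit indeterminate state, never zero.

## Regions and agreement statistics

Target contours are center-in-sphere voxel masks at each static position;
the wrap count is evaluated on their union over the position series (the
excursion envelope of the moving target, analogous to an internal target
volume). For lead setups the void around the lead is taken from the
averaged static map and `distance_shells` partitions its neighbourhood into
half-open 1-mm Euclidean distance bands (default 15), computed exactly
between voxel centers in physical mm via a separable squared-distance
transform (anisotropic-safe).

Agreement is quantified per configuration and per shell with Bland–Altman
statistics on voxel pairs (dynamic − static; the sign is recorded in the
output): mean difference, sample SD ($n-1$), the spread $1.96\,\mathrm{SD}$,
limits of agreement, and symmetric empirical-quantile central intervals
(50 % and 95 % by default, linear interpolation between order statistics) on
both axes — the "smallest region containing f of the data" used for
plotting; a 2-D highest-density construction is out of scope. Static maps
are averaged before differencing for lead setups; implant setups compare
each static position separately and pooled group-wise (concatenated pairs).
Spreads are converted to mm via the readout bandwidth and reported at two
decimals (round-half-even), full precision retained internally.

## Verdict

`decide_eligibility` is conservative and purely qualitative: **ineligible**
iff at least one wrap crosses the target area, **indeterminate** iff the
target is fully void, **eligible** otherwise. The spread in mm is reported
as supporting evidence but never thresholded — no clinically tolerable wrap
count or mm distortion is defined for this procedure, so none is invented.

## ECG artifact module

`synth_ecg` builds a clean single-lead trace from Gaussian P/Q/R/S/T
deflections whose offsets and widths scale with the RR interval (first R
peak at $t=0$; R deflections only for beats inside the window). Gradient
activity is a repeated trapezoid; the induced artifact is its derivative —
bipolar pulses at the ramps — normalised and scaled by a gain
(`artifact_model`). Two presets mirror which sequences left the ECG
readable in practice: slow 3-D planning sequences (sparse ramps, low gain)
versus fast multi-plane cine monitoring (dense ramps, high gain). The
printed monitor readings from the original measurements (193 bpm, 177 bpm,
"could not be determined") depend on proprietary firmware and a real
volunteer, so they are treated as behaviours to reproduce in kind, not
numeric targets.

`detect_hr` emulates a monitor: local maxima above an adaptive threshold
(0.6 × rolling 1-s maximum), a 250 ms refractory period, rate =
60/median(RR), and an unreliable flag when fewer than two peaks are found or
the RR dispersion (SD/median) exceeds 15 %. On clean traces it recovers
40–180 bpm within ±1 bpm; under the dense high-gain preset it either reports
a gross overestimate (the refractory-limited pulse rate) or flags itself
unreliable, and its absolute error is non-decreasing in the artifact gain.

## Numerical choices and problem sizes

* Half-open wrap interval $(-\pi, \pi]$, tested at the boundary.
* Ties in the unwrapping front broken by linear voxel index; voxel
  membership by center-in-region test; half-open distance bands $[lo, hi)$.
* Sample SD uses $n-1$; quantiles use type-7 linear interpolation.
* Empty shells yield explicit empty records; a single pair flags the SD as
  undefined rather than returning 0.
* The packaged pipeline configurations run on desk-scale grids chosen to
  keep every voxel of the analysis regions Nyquist-compliant
  (per-neighbour steps < π): implant setups on 64×64×48 at 3 mm, lead
  setups on 72×72×64 at 1 mm. Sources may lie outside the grid; their
  fields are evaluated analytically.
* `n_motion_phases = 16` resolves the cos⁴ cycle to a phase bias well below
  the acquisition noise floor (halving the step changes phases by < 0.08
  rad on smooth fields, asserted in the tests).

## What the simulation does and does not show

The generator emulates the study conditions of the phantom measurements the
procedure was validated on: a spherical water target moved through static
positions −10…+10 mm and under 20 mm peak-to-peak cos⁴ breathing, an
implant at 175/105/85 mm, and a helically wrapped lead under added cardiac
motion. It does not model k-space readout, ghosting, eddy currents, B1,
heating, or dose — so the *published* phantom numbers (groupwise mean
differences of 4/9/1/48 Hz; spreads of 39/42/149/161 Hz) are not
reproducible at desk scale and are not targets. What the tests do
establish, end to end: a zero-noise, zero-motion run is exactly null; the
spread grows strictly monotonically as the implant approaches the target
(the ordering the measurements show); the closest setup drives multiple
wraps through the target and an ineligible verdict; lead shell profiles
peak at the void and decay with distance. Real data add scanner-specific
inhomogeneity, susceptibility interfaces of anatomy, and sequence-specific
artifacts that this simulator deliberately leaves out.

## A worked run

```{r pipeline, eval = FALSE}
res <- run_pipeline(config_implant(85), seed = 5)
res$report
# <eligibility_report> implant_85mm
#   wraps in target : 3
#   verdict         : ineligible
#   mean diff       : 49.96 Hz
#   spread (1.96SD) : 401.88 Hz = 0.89 mm at 450 Hz/mm
```

The same pipeline is exposed on the command line
(`inst/cli/b0gate simulate|unwrap|analyze|report|all`), reading a YAML scene
configuration (examples under `inst/extdata/configs/`) and writing NIfTI
volumes, CSV agreement tables and a JSON report.

## Known limitations

* The dipole/superposition field model ignores implant geometry and
  material; it is a testable stand-in, not a susceptibility solver.
* Rigid scene motion ignores tissue deformation and any differential
  target-vs-implant motion.
* The complex-average dynamic model omits k-space effects (ghosting,
  view ordering), which dominate some real motion artifacts.
* Eligibility is wrap-presence only; a clinical implementation would add
  institution-specific margins and review.
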