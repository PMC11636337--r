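# b0gate

Screening patients with a cardiac implantable electronic device (CIED) for
MR-guided radiotherapy (MRgRT) of thoracic targets hinges on geometric
fidelity: the implant and its leads perturb the main magnetic field (B0),
and an off-resonance of Δf Hz displaces signal along the readout axis by
Δf / BW mm at readout bandwidth BW (450 Hz/mm is typical). A dual-echo
B0-map measures Δf voxel-wise, but it arrives wrapped modulo 2π·ΔTE and, in
the thorax, is acquired under respiratory motion.

`b0gate` implements the whole screening procedure as a reproducible R
pipeline:

* **Phantom simulation** — a water-filled spherical target near a point-dipole
  implant (Δf = k(3cos²θ−1)/r³) or a helically wrapped lead (dipole chain +
  tip dipole), moved rigidly by a cos⁴ respiratory pattern (20 mm
  peak-to-peak at 15 breaths/min, plus an optional cardiac component);
  wrapped dual-echo acquisitions with complex noise, intravoxel dephasing
  and complex time-averaging over the motion cycle.
* **Phase unwrapping** — deterministic quality-guided region growing driven by
  magnitude and phase; signal voids excluded; disconnected components
  referenced independently; exact 2π bookkeeping per voxel.
* **Agreement analysis** — voxel-wise static-vs-dynamic differences inside
  target contours and inside 1-mm Euclidean distance shells around the lead
  signal void; Bland–Altman mean difference, 1.96·SD spread, limits of
  agreement and central 50 %/95 % intervals.
* **Eligibility verdict** — conservative and qualitative: one or more phase
  wraps crossing the target area ⇒ *ineligible*; target fully void ⇒
  *indeterminate*; otherwise *eligible*. The spread in mm
  (spread_Hz / 450 Hz·mm⁻¹) is reported as supporting evidence.
* **ECG companion module** — synthetic PQRST traces, additive
  gradient-switching artifact (trapezoid-derivative pulse trains with
  sequence presets), and an adaptive-threshold heart-rate detector whose
  failure modes under dense high-gain artifact motivate pulse oximetry.

See `vignettes/b0-mapping-eligibility.Rmd` for the models, defaults and
design choices.

## Worked example

```r
library(b0gate)

# implant 85 mm from isocenter, default desk-scale grid (64x64x48 @ 3 mm)
res <- run_pipeline(config_implant(85), seed = 5)
res$report
#> <eligibility_report> implant_85mm
#>   wraps in target : 3
#>   verdict         : ineligible
#>   mean diff       : 49.96 Hz
#>   spread (1.96SD) : 401.88 Hz = 0.89 mm at 450 Hz/mm

head(res$position_table[, c("label", "n_pairs", "mean_diff_hz", "spread_hz")])
#>             label n_pairs mean_diff_hz spread_hz
#> 1 position -10 mm     508    105.16845  453.4297
#> 2  position -5 mm     503    101.61417  419.6316
#> 3  position +0 mm     532     68.05272  422.9399
#> 4  position +5 mm     522     32.53008  314.7851
#> 5 position +10 mm     517    -55.57683  289.0279
```

Three or more distinct 2π branches cross the target envelope: the B0-map in
the target area cannot be trusted, so this configuration is ineligible for
MRgRT. The pooled 1.96·SD spread of the dynamic-minus-static differences,
402 Hz, corresponds to 0.89 mm of geometric uncertainty at a 450 Hz/mm
readout. Moving the same implant to 175 mm leaves the target wrap-free
(verdict *eligible*, spread 14.4 Hz = 0.03 mm): the spread rises strictly
monotonically as the implant approaches the target.

The same pipeline runs from a shell via a thin CLI over the package
functions:

```sh
inst/cli/b0gate all --config inst/extdata/configs/implant_85mm.yaml --seed 5 --out out/
```

writing NIfTI volumes (unwrapped Hz map, wrap counts, magnitude), CSV
agreement tables and a JSON report.

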