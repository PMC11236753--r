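# festwin

A desk-scale digital twin for transcutaneous functional electrical
stimulation (FES) of the human forearm, with muscle-specific activation
resolution.

FES elicits hand movements through current pulses delivered by skin
electrodes, but selective activation of the many small, layered forearm
muscles is still an open problem. `festwin` is aimed at researchers and
engineers who want to study electrode positions and stimulation settings in
simulation before (or instead of) fatiguing experiments. It implements the
full simulation chain:

- **Volume conductor** — a parametric four-layer phantom (bone, anisotropic
  muscle, fat, skin) built from per-station cross-section ellipses, with
  hydrogel surface electrodes placed by axial/radial percentage coordinates.
  The quasi-static potential ∇·(σ∇V) = 0 is solved for unit current with a
  finite-volume scheme on a voxel grid (sparse Cholesky); space and time
  factorize, V(p, t) = V_unit(p)·I(t).
- **Fiber arrangement** — per-muscle elliptical regions of interest (ROIs)
  anchored at nerve entry points from a packaged literature table; each ROI
  holds 500 straight myelinated fibers with cross-sections uniform over the
  ellipse, diameters from a bimodal (5/11 µm) truncated-normal mixture on
  [2, 16] µm, and nodes of Ranvier at diameter-dependent spacing
  Δx(d): 2 µm → 155 µm, 16 µm → 1500 µm.
- **Nerve models** — the linear (McNeal-type) cable model
  dV_m/dt = (1/C_m)[G_a(Δ²V_m + Δ²V_e) − G_m V_m], integrated implicitly,
  with per-fiber threshold amplitudes in closed form by linearity; and the
  activating function Δ²V_e/Δx² with a diameter/pulse-width threshold table
  calibrated against the cable model.
- **Recruitment and calibration** — ROI activation fractions,
  strength–duration (SD) and intensity–activation curves, Weiss-hyperbola
  fits A(PW) = b(1 + c/PW), mean relative differences in 1 µs pulse-width
  steps, per-muscle activation-threshold selection over two pulse-width
  ranges, and defaults by range-wise averaging.

See `vignettes/festwin-methods.Rmd` for the model assumptions, numerical
choices and limitations.

## Worked example

Simulate the extensor carpi ulnaris (ECU) strength–duration curve with the
packaged electrode positions on the default phantom:

```r
library(festwin)

cfg <- default_config(muscles = "ECU", resolution_mm = 4, n_fibers = 100,
                      pw_list = c(50, 100, 200, 300, 500), ath = 0.20,
                      seed = 1)
rep <- run_pipeline(cfg, out_dir = "ecu-run")
rep$curves$ECU$points
#>   pw_us   amp_mA
#> 1    50 36.95221
#> 2   100 29.97584
#> 3   200 27.04494
#> 4   300 26.56448
#> 5   500 26.45860
```

The amplitudes are the smallest currents at which 20% of the ECU ROI's
fibers fire: they fall monotonically with pulse width and flatten toward a
rheobase near 26 mA — the characteristic SD shape. (Absolute values depend
on the synthetic default geometry; with an individual's station table and
ROI hints they become person-specific.)

Threshold calibration from the packaged relative-difference table:

```r
sel <- select_ath_table()
default_ath(sel)
#>  20-200 201-500
#>    0.20    0.12
```

A thin CLI wraps the same functions:
`inst/exec/fes-twin run|sd-curve|calibrate-ath|gen-experiment|... --seed 1`.

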