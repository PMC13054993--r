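# relaxomap

Voxel-wise MR relaxometry mapping and contrast-agent calibration in R.

`relaxomap` is a quantitative-MRI analysis pipeline for characterizing
iron-oxide nanoparticle contrast agents from multi-echo and
inversion-recovery acquisitions. It is aimed at preclinical imaging groups
who need the whole chain — phantom to parametric map to calibration line —
as tested, scriptable code:

* **Forward models.** Mono-exponential transverse decay
  `S(TE) = S0 exp(-TE/T2)`, bi-exponential decay
  `S(TE) = A1 exp(-TE/T2,fast) + A2 exp(-TE/T2,slow)` and inversion
  recovery `S(TI) = S0 (1 - beta exp(-TI/T1))`.
* **Synthetic data with ground truth.** A dilution-series agarose phantom
  (eight tubes, 0-100 µM Fe, 40 echoes 10-400 ms, (80, 100, 500) µm
  voxels) and an injected-tissue slab whose injection site decays
  bi-exponentially; Gaussian or Rician noise, fully seeded.
* **Voxel-wise fitting.** Damped Levenberg-Marquardt with analytic
  Jacobians, log-linear initialization, physical bounds, per-voxel failure
  flags (never fatal).
* **Model selection maps.** `AIC = n ln(RSS) + 2k`,
  `BIC = n ln(RSS) + k ln(n)`; the bi-exponential model is accepted where
  the criterion differences exceed 10 (AND rule by default, OR available),
  producing fast/slow T2 maps and a binary dual-component map.
* **Calibration.** OLS relaxivity vs iron concentration, agarose
  background-rate subtraction, 3-sigma limit of detection
  `LOD = 3 sigma_blank / slope`, iron quantification from
  `R1 = Rdia + [Fe] r1p` (defaults 0.52 s^-1 and 1.29 mM^-1 s^-1), NMRD
  profile assembly (42.577 MHz/T) and field-regime / r2-r1 contrast-agent
  classification.
* **ROI dynamics.** Enhancement time courses
  `[(post - pre)/pre] x 100` and blank-corrected organ iron (µg/g).
* **I/O.** Uncompressed NIfTI-1 volumes with a plain-text echo-time
  sidecar, CSV tables, JSON summaries and a manifest-writing CLI
  (`inst/cli/relaxomap`).

## Worked example

```r
library(relaxomap)

# noiseless dilution-series phantom -> voxel-wise T2 map -> calibration
sim  <- generate_phantom(phantom_spec())
fits <- fit_volume(sim$volume, bi = FALSE)
r2   <- 1000 / fits$mono_t2                         # T2 [ms] -> R2 [s^-1]
tube_r2 <- sapply(1:8, function(k) mean(r2[sim$truth$labels == k]))
bg      <- mean(r2[sim$truth$labels == 0])          # agarose background
fit_calibration(concentration_series(sim$truth$tubes$fe_mM,
                                     subtract_background(tube_r2, bg)),
                sigma_blank = 0.5)
#> <calibration_fit> rate = 145 * [Fe] + 1.822e-15  (r^2 = 1.00000, n = 8)
#>   LOD (3 sigma, sigma_blank = 0.5 s^-1): 0.01034 mM (10.3 uM)
```

The slope is the transverse relaxivity (145 mM^-1 s^-1 for the default
phantom), the intercept is zero after background subtraction, and the
3-sigma limit of detection with the 0.5 s^-1 blank SD is ~0.0103 mM, i.e.
10 µM once rounded.

```r
# injected slab at 2% noise -> mono/bi fits -> binary dual-component map
inj  <- generate_injection_volume(injection_spec(noise_sd = 2, seed = 1))
maps <- fit_maps(inj$volume)$maps
table(map = maps$binary_map, truth_bi = inj$truth$labels == 2)
#>    truth_bi
#> map FALSE TRUE
#>   0   974    0
#>   1     1   49
```

All 49 injection-site voxels pass the dual-component criterion; one of the
975 mono-exponential voxels is a false positive at this noise level and
seed (99.9% accuracy).

## Documentation

The methods vignette (`vignettes/relaxometry-pipeline.Rmd`) documents the
models, the synthetic world and its limits, the numerical choices of the
fitting engine, and known limitations.
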