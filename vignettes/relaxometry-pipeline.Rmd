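---
title: "Quantitative relaxometry of nanoparticle contrast agents with relaxomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative relaxometry of nanoparticle contrast agents with relaxomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxomap)
```

## The problem

Iron-oxide nanoparticle contrast agents shorten the transverse relaxation
time T2 of nearby water protons. Characterizing such an agent
quantitatively requires a chain of analyses that this package implements as
one tested pipeline:

1. **Voxel-wise T2 mapping.** A multi-slice multi-echo (MSME) acquisition
   yields one image per echo time TE. Each voxel's magnitude decay is fitted
   with a mono-exponential model
   $S(\mathrm{TE}) = S_0 e^{-\mathrm{TE}/T_2}$
   and a bi-exponential model
   $S(\mathrm{TE}) = A_1 e^{-\mathrm{TE}/T_{2,1}} + A_2 e^{-\mathrm{TE}/T_{2,2}}$,
   the latter capturing the heterogeneous microenvironment near magnetic
   particles (a fast pool close to the particles, a slow bulk-like pool).
2. **Model selection.** Mono vs bi is decided per voxel with
   $\mathrm{AIC} = n\ln(\mathrm{RSS}) + 2k$ and
   $\mathrm{BIC} = n\ln(\mathrm{RSS}) + k\ln(n)$, the bi model being
   accepted when the criterion differences exceed 10. Binary maps of the
   accepted voxels localize dual-component relaxation.
3. **Relaxivity calibration.** Tube-wise rates $R_2 = 1/T_2$ from a
   dilution-series phantom are regressed on iron concentration; the slope is
   the relaxivity $r_2$ (mM⁻¹ s⁻¹) and the 3σ limit of detection is
   $\mathrm{LOD} = 3\sigma_\mathrm{blank}/\mathrm{slope}$.
4. **Iron quantification and NMRD.** Longitudinal rates from
   inversion-recovery (IR) measurements invert the standard curve
   $R_1 = R_\mathrm{dia} + [\mathrm{Fe}]\, r_{1p}$ (defaults
   $R_\mathrm{dia} = 0.52\ \mathrm{s^{-1}}$,
   $r_{1p} = 1.29\ \mathrm{mM^{-1}s^{-1}}$); dispersion measurements across
   field strengths assemble into an NMRD profile
   (frequency $= 42.577\ \mathrm{MHz/T} \times$ field).
5. **ROI contrast dynamics.** Organ time courses are summarized with
   $[(\mathrm{post}-\mathrm{pre})/\mathrm{pre}] \times 100$; T2 agents
   darken tissue, so the signed enhancement is negative and its magnitude is
   what uptake plots display.

No measured dataset ships with the package; every downstream stage is
exercised on synthetic volumes with known ground truth.

## The synthetic world

`phantom_spec()` describes a dilution-series phantom: eight tubes (water
control plus 2.5, 5, 10, 25, 50, 75 and 100 µM Fe) as cylinders on a ring
in 1% agarose, a 64×64×4 grid at (80, 100, 500) µm voxels, imaged with 40
echoes evenly spaced 10–400 ms. Tube rates follow
$R_2 = 7 + 145\,[\mathrm{Fe}]\ \mathrm{s^{-1}}$ by default, the agarose
background relaxing at the intercept alone. Choices the acquisition
description leaves open were fixed once:

* **Tube geometry** (ring of cylinders, radius 3 voxels) is visual
  plumbing; the calibration statistics only depend on the per-tube rates.
* **Proton density** is a constant 100 a.u. in every compartment — no coil
  profile, no partial-volume effects.
* **Noise** is Gaussian by default (zero-mean, additive, unclipped — signed
  samples survive, which is what least squares should be tested against); a
  Rician option models magnitude images, never negative and Rayleigh on
  zero-signal background. A realistic magnitude-image SNR for such scans is
  of order 50, i.e. `noise_sd` ≈ 2 for `s0 = 100`, which is the level the
  selection-accuracy acceptance test uses.
* **Water as the eighth tube.** The dilution list has seven non-zero
  levels; the 0 mM water control is counted as the eighth tube.

`injection_spec()` emulates an injected ex-vivo brain slab: an
injection-site disc decaying bi-exponentially (defaults
$A_1 = A_2 = 50$, $T_{2,\mathrm{fast}} = 20$ ms,
$T_{2,\mathrm{slow}} = 200$ ms), a mirrored contralateral control disc and
surrounding tissue decaying mono-exponentially. The control-tissue T2
defaults to 120 ms: with equal-amplitude 20/200 ms components the injected
voxels retain $\approx 31\%$ of their signal at TE = 100 ms, so a control
must sit above $\approx 85$ ms for the injected site to show the faster
net transverse relaxation that motivates the bi-exponential reading; 120 ms
also keeps the control clearly separated from both components.

What a green test on this world does **not** establish: robustness to
B0/B1 inhomogeneity, slice profiles, echo-train (RARE) blurring, Rician
bias at low SNR, partial-volume mixing at tube walls, or motion. The
generators deliberately exclude all of these.

## Fitting engine and numerical choices

All fits run a small damped Levenberg–Marquardt routine with analytic
Jacobians (`R/optim-lm.R`) — the same algorithm family as MATLAB's
`lsqcurvefit` used in the original analysis. Base R's `nls()` cannot be
used as the engine because it rejects zero-residual (noiseless) curves,
which are exactly the ground-truth round-trip cases the pipeline must pass.

* **Initialization.** Mono: ordinary least squares of $\log S$ on TE over
  the positive samples. Bi: from the mono fit as
  $A_1 = A_2 = S_0/2$, $T_{2,\mathrm{fast}} = T_2/2$,
  $T_{2,\mathrm{slow}} = 2T_2$. IR: $T_1$ from the sampling time nearest
  the null point divided by $\ln 2$.
* **Bounds.** $T \in [1, 5000]$ ms, amplitudes $\in [0, 10\times]$ the
  largest observed signal, enforced by step projection. These stop the
  optimizer escaping along flat residual valleys.
* **Convergence.** Relative RSS change below $10^{-8}$ or 500 iterations;
  per-voxel failures are flagged, never fatal, so whole-volume maps always
  complete.
* **Degenerate components.** A bi fit whose components collapse
  ($T_{2,\mathrm{slow}}/T_{2,\mathrm{fast}} < 1.2$ or an amplitude below 1%
  of the total) is flagged *effectively mono* and never selected, whatever
  its information criteria. If the 4-parameter fit ends above the mono RSS
  (a nesting violation the optimizer cannot justify), the mono solution is
  substituted as a degenerate bi fit.
* **RSS floor.** Before the logarithm in AIC/BIC, RSS is floored at
  $10^{-12}\, n\, S_\mathrm{max}^2$; noiseless fits then land on a common
  floor where the deltas reduce to the pure parsimony penalties
  ($\Delta\mathrm{AIC} = -4$), so noiseless mono voxels are classified
  correctly instead of producing $\ln 0$.
* **`n ln(RSS)` as printed.** The criteria use RSS, not RSS/n. At fixed
  $n$ the two differ by a constant, so the mono/bi ranking per voxel is
  unaffected; the printed form is implemented verbatim.
* **Selection rule.** The text criterion ("ΔAIC **or** ΔBIC > 10") and the
  map criterion (both exceed 10) differ; both are implemented and the
  conservative AND rule is the default for binary maps. With $k$ counted
  as 2 (mono) and 4 (bi) and $n = 40$, ΔBIC < ΔAIC always, so OR and AND
  only disagree in a narrow band of evidence.
* **Sign convention.** Deltas are criterion(mono) − criterion(bi):
  positive favors the bi model.
* **Background subtraction** acts on fitted rates, not raw signals, and is
  a plain difference: blank replicates may go slightly negative and are
  kept, so the blank SD feeding the LOD stays honest. The same policy
  applies to iron concentrations recovered below the diamagnetic rate and
  to blank-corrected organ iron.
* **IR model form.** The recovery equation is not printed in the source
  description; the standard $S(\mathrm{TI}) = S_0(1 - \beta
  e^{-\mathrm{TI}/T_1})$ is adopted with ideal inversion $\beta = 2$ fixed
  by default and optionally free in $[1, 2]$, which also covers
  magnitude-valued recovery curves (`magnitude = TRUE` fits through
  $|S|$). Whether the original fits used signed or magnitude recoveries is
  unstated, so both routes exist and are tested.

## Identifiability limits worth knowing

* With echoes confined to 10–400 ms, a compartment with $R_2 \lesssim 2$
  s⁻¹ ($T_2 \gtrsim 500$ ms) barely decays inside the train; its fitted
  $T_2$ presses against the 5000 ms bound. The end-to-end
  slope-recovery guarantee therefore holds for backgrounds whose blank
  tube still decays measurably — the shipped tests use intercepts of 2–20
  s⁻¹ — and a water-only phantom with no agarose loading would need longer
  echo trains.
* IR curves sampled only well after the null point ($\mathrm{TI} \gtrsim
  5T_1$) are flat; the fitter converges but flags the result
  `ill_conditioned` (Jacobian condition number above $10^6$).
* At matched RSS the bi model can only lose (parsimony penalties), so
  binary maps are conservative by construction; the threshold of 10 makes
  false-positive dual-component voxels rare even at 2% noise.

## File formats

Volumes travel as uncompressed NIfTI-1 plus a plain-text sidecar
(`<stem>_times.csv`, columns `index`, `time_ms`) because echo times do not
fit in a NIfTI header. The pre-installed R stack has no NIfTI package, so a
minimal codec (float64/float32/int, diagonal sform, no extensions) is built
in; write/read round trips are bit-exact and the on-disk layout is
cross-checked against nibabel in the test suite. Tables are CSV, summaries
and manifests JSON; `write_outputs()` records stage, seed and a
configuration hash so that reruns are reproducible modulo timestamps.

## Worked example

```{r example, eval = FALSE}
library(relaxomap)

# dilution-series phantom -> voxel T2 fits -> calibration
sim  <- generate_phantom(phantom_spec())
fits <- fit_volume(sim$volume, bi = FALSE)
r2   <- 1000 / fits$mono_t2
tube_r2 <- sapply(1:8, function(k) mean(r2[sim$truth$labels == k]))
bg      <- mean(r2[sim$truth$labels == 0])
cal <- fit_calibration(
  concentration_series(sim$truth$tubes$fe_mM,
                       subtract_background(tube_r2, bg)),
  sigma_blank = 0.5)
cal                      # slope 145 mM^-1 s^-1, LOD ~10.3 uM

# injected slab -> mono/bi fits -> binary dual-component map
inj  <- generate_injection_volume(injection_spec(noise_sd = 2, seed = 1))
maps <- fit_maps(inj$volume)$maps
table(maps$binary_map, inj$truth$labels == 2)
```

## Known limitations

The pipeline fits magnitude signals with unweighted least squares: no
Rician noise-floor correction, no weighting, no spatial regularization of
the maps, and at most two candidate models per voxel (no AICc, no
three-pool models). The NMRD module assembles and classifies measured
dispersion points but fits no physical dispersion theory to them. DICOM
and vendor formats are out of scope; conversion to NIfTI is assumed.
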