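---
title: "Modelling NIR-heated photoseed thermotherapy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling NIR-heated photoseed thermotherapy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoseed)
```

## The problem this package models

Interstitial thermotherapy heats a tumour from within, via implanted
heat sources, to hyperthermic (41--45 °C) or ablative (>50 °C) levels.
*Photoseeds* are implantable plasmonic nanocomposite rods — gold
nanoparticles dispersed in a PDMS matrix — that convert near-infrared
(810 nm) laser light into heat at the implant site. This package simulates
the coupled optics--heat--damage chain for an array of photoseeds in layered
breast tissue, and implements the lumped photothermal calorimetry used to
characterise the nanocomposites on the bench.

The simulation pipeline has three stages, executed by `run_invivo()`:

1. **Light.** A continuous-wave beam enters the tissue and its fluence
   field is evaluated under the optical diffusion approximation,
   $\phi(\vec r) = P_0 \exp(-\mu_{eff}\, \vec r\cdot\hat n)\,/\,(4\pi D r)$,
   with $D = 1/(3(\mu_a+\mu_s'))$ and
   $\mu_{eff} = \sqrt{3\mu_a(\mu_a+\mu_s')}$. The volumetric heat source is
   $q = \mu_a \phi$, where photoseed voxels use the bulk absorption
   coefficient derived from the measured absorbance,
   $\mu_a = 2.303\,A_{810}/l$.
2. **Heat.** The Pennes bioheat equation
   $\rho c\,\partial T/\partial t = \nabla\!\cdot(\lambda(T)\nabla T) +
   \rho_b c_b \omega_b(\Omega)(T_b - T) + Q_{met} + q$
   is integrated with temperature-dependent conductivity
   $\lambda(T) = \lambda_{37}[1 + 0.0028\,(T - 293.15\,\mathrm{K})]$ and
   damage-dependent perfusion $\omega_b(\Omega)$ (baseline, a transient
   hyperaemic rise up to 1.6x for $0<\Omega\le 0.1$, linear shutdown to
   stasis at $\Omega = 1$).
3. **Damage.** First-order Arrhenius injury kinetics
   $\Omega(\tau) = A\int_0^\tau \exp(-E_a/RT(t))\,dt$ accumulate cell
   damage; $\Omega = 1$ marks complete irreversible damage, and lesion
   metrics (volume, crossing times, radial profiles) summarise the field.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| fat $\mu_a$, $\mu_s'$ | 3, 950 | m$^{-1}$ | literature breast-fat optics |
| gland $\mu_a$, $\mu_s'$ | 6, 1100 | m$^{-1}$ | literature gland optics |
| seed $A_{810}$, $l$ | 1.54, 30 | --, µm | 10 wt.% Au nanocomposite; gives $\mu_a \approx 1.18\times10^5$ m$^{-1}$ |
| fat $c,\lambda,\rho,Q_{met},\omega_{b0}$ | 2348, 0.21, 911, 400, 2e-4 | SI | |
| gland $c,\lambda,\rho,Q_{met},\omega_{b0}$ | 2960, 0.48, 1041, 700, 5e-4 | SI | |
| blood $\rho_b, c_b$ | 1050, 3617 | SI | perfusion term |
| Arrhenius $A$, $E_a$, $R$ | 1.18e44, 3.02e5, 8.3 | s$^{-1}$, J mol$^{-1}$, J mol$^{-1}$K$^{-1}$ | $R$ kept at the printed 8.3, not 8.314; configurable |
| seed array | 2x2, $s$ = 5 mm, $d_s$ = 1 mm, $L$ = 15 mm | | axes along the beam |
| block, fat layer | 6x6x6 cm, 1 cm | | see below |
| $P_0$ | 0.5--2 W | W | parametric study range |
| dt, duration | 0.5 s, 900 s | s | implicit stepping; dt is accuracy only |

Where the underlying study left a value unstated we chose once and exposed
it in configuration:

* **Block dimensions and fat:gland split.** Never quantified (only "BIRADS
  proportions"); we use a 6 cm cube with a 1 cm superficial fat layer,
  which keeps the seed array deep in gland. The plateau timing of the P1
  trace moves by under 10% when the block shrinks to 4 cm, though peak
  temperatures rise strongly as the array nears the illuminated face.
* **Seed thermo-physical properties.** Absent from the source tables; we
  use literature PDMS values ($\rho$ = 970 kg m$^{-3}$, $c$ = 1460
  J kg$^{-1}$K$^{-1}$, $\lambda$ = 0.16 W m$^{-1}$K$^{-1}$), zero perfusion
  and zero metabolic heat (it is an implant).
* **Boundary conditions.** "Specified as outlined above" outlines none; we
  default to fixed body-core temperature (37 °C) on the block's outer faces
  in vivo — the standard far-field hyperthermia assumption — and a
  convective boundary ($h$ = 10 W m$^{-2}$K$^{-1}$, free convection to
  25 °C ambient) for the bench model.
* **Conductivity reference.** The printed conductivity law pairs
  $\lambda(37°C)$ with a 293.15 K (20 °C) reference; we implement it
  literally and expose `lambda_Tref` for users who believe 310.15 K was
  intended.
* **Fluence at seed voxels.** The diffusion kernel needs $\mu_{eff}$ and
  $D$, but the seed has no scattering data, and its absorbance-derived
  $\mu_a$ is so large that a literal local-kernel evaluation underflows to
  zero fluence (no heating at all). Since a millimetre-scale implant
  perturbs the tissue photon field negligibly, seed voxels evaluate the
  kernel with the host gland's optics while keeping $\mu_a^{seed}$ in the
  source term. Tissue voxels use their own local properties, as printed;
  `mode = "integrated"` switches to a ray-averaged $\mu_{eff}$, the
  physically truer reading across the fat/gland interface.
* **Bench validation source.** Water is essentially transparent and
  non-scattering at 810 nm, so the turbid-medium kernel is invalid there;
  the validation run instead deposits the absorbed power
  $P_0(1-10^{-A_{810}})$ uniformly in the seed volume, consistent with the
  calorimetry energy balance.

## Numerical scheme

Time stepping is implicit (backward Euler), so it is unconditionally stable
at seed-resolving grids where explicit stepping would need millisecond
steps; `dt` purely controls accuracy. The two nonlinearities,
$\lambda(T)$ and $\omega_b(\Omega)$, are lagged one step, making each step
a symmetric positive-definite linear solve, handled matrix-free by
Jacobi-preconditioned conjugate gradients warm-started from the previous
field (5--10 iterations per step at a relative tolerance of 1e-10). Face
conductivities are harmonic means, which keeps the heat flux continuous
across the seed--tissue interface where $\lambda$ jumps by a factor of
three. Damage is accumulated by trapezoidal quadrature of the Arrhenius
rate every step — exact at constant temperature, second-order otherwise —
and feeds back into perfusion each step in the default two-way mode;
`coupling = "one-way"` reproduces the strictly sequential
temperature-then-damage pipeline (the two agree exactly while
$\Omega \approx 0$).

Other numerical choices:

* The point-source kernel diverges at $r = 0$; $r$ is clamped at half a
  voxel spacing, affecting only the beam-entry voxel.
* Voxels are assigned materials by centre-point membership; the voxelized
  seed volume converges first-order to the analytic cylinder volume, and a
  configuration whose seed axis falls so far between voxel centres that a
  seed would contain no voxels is a hard error, not a silent omission.
* A per-step global energy balance (storage vs. sources, perfusion and
  boundary flux, with interior fluxes cancelling by construction) is
  recorded in the run diagnostics; it closes to the CG tolerance.
* `refine_to_asymptote()` re-solves a problem at successively finer
  spacings until the monitored interface temperature stops changing,
  erroring if the level-over-level changes grow across three refinements.
* The conductivity law is clamped at a configurable floor (default 1e-3
  W m$^{-1}$K$^{-1}$, with a warning) so unphysically cold inputs cannot
  produce a negative diffusion operator.

## The synthetic-data generators

`make_heating_curve()` emulates IR-camera records of the bench experiments:
a saturating exponential $T(t) = T_0 + \Delta T_\infty(1 - e^{-t/\tau})$ —
the simplest family matching the observed fast-rise-then-plateau shape —
plus i.i.d. Gaussian noise (default sd 0.1 °C at 1 Hz, the class of noise a
compact thermal camera produces). Every curve carries its generating
parameters and analytic initial slope as a ground-truth attribute, and the
same seed reproduces the same curve bit-for-bit without touching the global
RNG stream. What the generator does *not* emulate: sensor drift,
emissivity error, convective plumes disturbing the surface reading, or the
cool-down segment after laser-off. Passing recovery tests therefore shows
the analysis chain is correct and noise-robust, not that real IR records
are this well-behaved.

`make_toy_phantom()` supplies solver-verification fixtures with their
references attached: a conduction slab whose steady centre rise is
$QL^2/8\lambda$ (perfusion and metabolic heat stripped, since the closed
form assumes pure conduction), a single-seed block for monotone-decay
checks, and the bench water model.

## Problem sizes used by the tests

Unit tests run on bars and blocks of at most ~3 x 10^4 voxels and seconds
of simulated time. The end-to-end checks use the study conditions
themselves: the default 60^3-voxel phantom for 15 simulated minutes per
laser power (about 40 s of wall time per power with the compiled solver),
which we consider the natural verification scale since it is exactly the
configuration the headline results use. The plateau-timing quantity
reported by `scripts/acceptance.R` is computed from that same default run.

## Known limitations

* No phase change: temperatures above 100 °C can occur inside seeds and
  near the beam entry at high power and are reported as-is.
* The diffusion approximation is poor within ~1 transport mean free path of
  the source and in low-scattering media; the bench model avoids it
  entirely (uniform seed deposition) rather than pretending otherwise.
* Optical properties do not change with damage, and the water model is
  conduction-only (no convection in the tube).
* The damage model is the single-threshold Arrhenius integral; no CEM43
  dose or cell-line-specific parameter fitting.
* The trypan-blue arithmetic is reported in both orientations because the
  source convention is internally contradictory; the package never decides
  which reading was intended.
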