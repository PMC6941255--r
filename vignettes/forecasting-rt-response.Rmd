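---
title: "Forecasting tumor and vasculature response to radiotherapy: models, calibration and validation"
author: "rtforecast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting tumor and vasculature response to radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(rtforecast)
```

## The modelling problem

`rtforecast` implements a family of image-driven, mechanically-coupled
reaction-diffusion models of glioma growth and response to single-fraction
whole-brain radiotherapy. The state consists of two co-registered 3D fields
on an MRI voxel grid: the tumor cell volume fraction $\phi_T(\bar x, t)$
(derivable from diffusion-weighted MRI via an apparent-diffusion-coefficient
map) and the blood volume fraction $\phi_V(\bar x, t)$ (derivable from
dynamic contrast-enhanced MRI as a tissue-to-artery area-under-curve ratio).
Given fraction maps at seven measurement days (10, 12, 14, 16.5, 18.5, 20.5,
22.5, with irradiation at day 14.5), the workflow is: calibrate each of ten
candidate models per subject on the first five time points, select one model
for the cohort by corrected-AIC average rank, then forecast the two held-out
time points and score the forecasts at the global (tumor volume error, Dice
overlap) and voxel (concordance correlation) levels.

## Governing equations

Tumor cells diffuse and proliferate logistically against a carrying capacity
shared with the vasculature:

$$\frac{\partial \phi_T}{\partial t} =
  \nabla \cdot \left( D_T \nabla \phi_T \right)
  + R_{LT}(t)\, k_{p,T}\, \phi_T
    \left( 1 - \frac{\phi_T + \phi_V}{\theta_{T,V}} \right),$$

where $\theta_{T,V} = \theta_T(\phi_V) + \theta_V$ combines the
vascularity-dependent tumor carrying capacity with the maximum blood volume.
$\theta_T$ is piecewise linear in $\phi_V$: equal to $\theta_{\max}$ wherever
$\phi_V \ge \phi_{V,\mathrm{thresh}}$ and falling linearly to
$\theta_{\min}$ as $\phi_V \to 0$ — poorly vascularized tissue supports
fewer cells.

Diffusion is damped exponentially by mechanical stress: tissue displacement
$\vec u$ solves the linear-elastic, isotropic equilibrium

$$\nabla \cdot G \nabla \vec u
  + \nabla \frac{G}{1 - 2\nu} (\nabla \cdot \vec u)
  - \lambda_2 \nabla \phi_T = 0,$$

with slip conditions at the brain boundary (zero normal displacement, free
tangential motion), and the von Mises stress $\sigma_{vm}$ of the resulting
stress tensor sets $D_T = D_{T,0}\, e^{-\lambda_1 \sigma_{vm}}$ (identically
for $D_V$).

The vasculature diffuses, grows by angiogenesis at the tumor periphery, and
dies in the tumor interior:

$$\frac{\partial \phi_V}{\partial t} =
  \nabla \cdot \left( D_V \nabla \phi_V \right)
  + R_{LT,V}(t)\, k_{p,V}\, d\, \phi_V \left( 1 - \frac{\phi_V}{\theta_V} \right)
  - k_{d,V} (1 - d)\, \phi_V,$$

where $d \in [0, 1]$ is the normalized distance to the tumor periphery
(1 at the tumor edge, 0 at its deepest voxel, computed as an exact
anisotropic Euclidean distance transform in physical mm and rescaled
linearly). **Design choice:** the two $d$-modulated reaction terms act only
inside the tumor mask, where $d$ is meaningful; outside the tumor, $\phi_V$
evolves by diffusion alone. Extending the death term to the whole brain
(with $d = 0$ there) would drain healthy vasculature everywhere, which
contradicts the persistent high blood volume observed at the brain surface;
restricting the reactions to the tumor keeps the healthy background stable.

## Radiotherapy response

Irradiation at day $t_{rt}$ with dose $D$ acts on two time scales. The
immediate effect removes a fraction of both fields at the instant of
delivery, $\phi^{post} = \phi^{pre} - \alpha_I\, C_I\, \phi^{pre}$ (the
vascular field is reduced with the same structure and, by default, the same
efficacy). The long-term effect multiplies the net proliferation of both
species by a piecewise factor $R_{LT}(t) = \alpha_{LT} C_{LT}$ for
$t \ge t_{rt}$ and 1 before. Five couplings define $C_I$ and $C_{LT}$:

| id | name | $C_I$ | $C_{LT}$ | calibrated |
|----|------|-------|----------|------------|
| C1 | logistic | $1 - \phi_T/\theta_T$ | $= C_I$ | $\alpha_I, \alpha_{LT}$ |
| C2 | linear-quadratic | $1 - e^{-\alpha D - \beta D^2}$ | $1 - C_I$ | $\alpha$ |
| C3 | vascular | $e^{-(\theta_V - \phi_V)\alpha_3}$ | $1 - C_I$ | $\alpha_I, \alpha_{LT}, \alpha_3$ |
| C4 | oxygen-enhanced | $1 - e^{\mathrm{OER}(-\alpha D - \beta D^2)}$ | $1 - C_I$ | $\alpha$ |
| C5 | uniform | $1$ | $1$ | $\alpha_I, \alpha_{LT}$ |

For C2 and C4 the efficacies are fixed at $\alpha_I = \alpha_{LT} = 1$ and
$\beta = \alpha / 14$ (an $\alpha/\beta$ ratio of 14); C4's oxygen
enhancement ratio is $\mathrm{OER} = \phi_V / \bar\phi_{V,pre}$ with
$\bar\phi_{V,pre}$ the mean $\phi_V$ over the tumor ROI across the
pre-treatment time points (the averaging domain is a package choice; the
quantity is exposed as an input). C3's parameter roles are a package
decision: $\alpha_3$ joins $\alpha_I, \alpha_{LT}$ as a free parameter.
The coupling fields are evaluated from the state at the instant of
irradiation and $C_{LT}$ is then frozen (configurable via
`recompute_CLT`), matching the piecewise-constant structure of the
long-term factor. Crossing the two k_pV parameterizations (global scalar vs
locally calibrated field) with the five couplings yields the ten models.

## Numerics

Both transport equations are advanced with a fully explicit forward-Euler
scheme at $\Delta t = 0.01$ d on the anisotropic voxel grid
($0.25 \times 0.25 \times 1$ mm at full scale), with central-difference,
flux-conservative diffusion (harmonic-mean face diffusivities — the
conservative standard for heterogeneous media) and no-flux (Neumann)
conditions at the brain-mask surface. With reactions off, the grid sum of
each species is conserved to machine precision; with diffusion off the
per-voxel solution matches the closed-form logistic to $10^{-3}$ relative
over 10 days (both are enforced in the test suite). A CFL check
($2 \max D\, \Delta t \sum_a h_a^{-2} < 1$) guards every run.

The elasticity operator is assembled once per (grid, $G$, $\nu$) as a sparse
symmetric positive-definite system — the grad-div term in its adjoint
(weak) form, which coincides with composed central differences in the
interior — and factorized by sparse Cholesky; each refresh then costs one
pair of triangular solves. The slip boundary is realised voxelwise: the
displacement component normal to a mask face is pinned to zero by symmetric
elimination, tangential components keep a traction-free (zero-gradient)
closure. Solves are verified against brute-force dense solutions of the
same discrete operator to $10^{-10}$.

Because the elasticity solve dominates cost while $\phi_T$ changes by well
under 1% per step, the stress field (and the distance-to-periphery field,
whose tumor mask is $\phi_T \ge \theta_{\min}$ by default) is refreshed on a
cadence of `mechanics_cadence` transport steps — 10 by default; the
calibration experiments shipped with the package use 25 (0.25 d), at which
the refreshed diffusivities are indistinguishable from the per-step values
at the phantoms' rates. Voxel fractions floored at 0 by round-off are
counted in the run log, never silently clipped; excursions above the
carrying capacities abort the run (or warn, if `stability_check = FALSE`)
rather than being hidden.

Tissue properties default to $G = 2100$ Pa and $\nu = 0.45$ uniformly in
brain — explicit, configurable inputs (per-label tables are supported), not
fitted quantities.

## Calibration

Each subject-model pair is fitted to time points 2-5, with time point 1 as
the initial condition, by minimizing the sum of squared errors of both
fields over an evaluation mask (the union of measured tumor masks over the
calibration window, dilated by two voxels). The optimizer is a hybrid
simulated-annealing Levenberg-Marquardt scheme: LM steps from a
central-difference Jacobian (1% relative steps on the transformed scale);
downhill proposals are always accepted, uphill ones with Metropolis
probability $e^{-\Delta SSE / T}$ under a geometric temperature schedule
($T_0$ = 10% of the initial SSE, cooling $\times 0.9$ per iteration — the
schedule knobs are exposed in `calibration_control()` rather than asserted
as unique). Iteration stops when successive accepted objectives change by
less than 0.5% or at 1000 iterations. Positive parameters are optimized in
log space and bounded ones in scaled-logit space, so the unconstrained LM
step respects physical bounds.

Assigned quantities follow the measurement-driven convention:
$\theta_{\min}$ is the lowest in-tumor $\phi_T$ and $\theta_V$ the largest
$\phi_V$ observed over the calibration window. Parameter-recovery
experiments on synthetic data instead pass the generating values through
the `assign` argument and use the truth field at time point 1 as the
initial condition — otherwise the experiment measures assignment noise and
the growth-amplified noise of the initial map rather than optimizer
behaviour.

For locally parameterized models, k_pV is calibrated at the corners and
centre of each 3x3 in-plane voxel block tiling the tumor bounding box, and
the remaining voxels copy their nearest calibrated site (ties broken by
site order: corners column-major, then centre); partial edge blocks
calibrate all their tumor voxels directly. Each coarse value counts as one
calibrated parameter.

## Model selection and evaluation

Model comparison uses the small-sample-corrected AIC,
$2k + n \ln(RSS/n) + 2k(k+1)/(n-k-1)$, computed jointly over both species
(the objective is joint, so one AIC per fit), with $n$ counting every
residual (mask voxels x 4 time points x 2 fields — a documented,
configurable convention) and $k$ every individually calibrated scalar.
Models are ranked 1-10 within each subject, ranks are averaged across
subjects (exact ties share the mean rank), and the lowest average rank wins
(ties broken by first-place counts, then mean AIC).

Forecasts re-run the full trajectory from time point 1 with frozen
calibrated parameters (a flag allows restarting from the last calibrated
state instead) and are scored per held-out time point by: signed percent
tumor volume error, Dice overlap of masks thresholded at $\theta_{\min}$
(the binarization level is configurable — the threshold used is recorded in
every report), and Lin's concordance correlation of each field over the
union of predicted and measured tumor masks, which penalizes false
positives and false negatives symmetrically. Two empty masks are defined to
have Dice 1.

## Synthetic phantoms

No subject data ship with the package, so a generator
(`phantom_spec()` / `make_phantom()` / `generate_measurements()`) produces
phantoms with the study's structure: an ellipsoidal brain, a smooth radial
tumor seed, an initial blood volume profile decaying from 0.20 at the brain
surface to 0.03 at depth (length scale 3 mm) — mirroring the high
vascularity at the brain-skull interface — and truth trajectories evolved
under a chosen generating model. Generating defaults ($k_{p,T} = 0.5$/d,
$k_{p,V} = 0.25$/d, $k_{d,V} = 0.15$/d, $D_{T,0} = 0.05$,
$D_{V,0} = 0.02$ mm²/d, $\lambda_1 = 2\times10^{-3}$/Pa,
$\theta_{\max} = 0.85$, $\theta_{\min} = 0.05$, $\theta_V = 0.22$,
$\phi_{V,\mathrm{thresh}} = 0.10$, C3 coupling with $\alpha_I = 0.6$,
$\alpha_{LT} = 0.75$, $\alpha_3 = 6$, 40 Gy at day 14.5) are chosen once as
plausible rodent-glioma scales: a doubling time under two days, tumor
diffusion well inside the explicit-stability region, and radiotherapy
efficacies that produce a visible but not annihilating response.
Measurement noise is additive Gaussian on the fraction maps, truncated to
[0, 1] ($\sigma = 0.02$ by default; the recovery experiments use 0.01).
Noisy cellularity maps are by default supported on the tumor ROI — the ADC
map they derive from is estimated within the ROI, so $\phi_T$ is zero
elsewhere — while blood volume maps carry noise across the whole brain; the
noiseless path returns the exact truth fields for closure experiments.
`phiT_roi_only = FALSE` switches to whole-brain additive noise on $\phi_T$:
the parameter-recovery experiments use this idealized measurement model
because under ROI support the truth-parameter trajectory no longer
minimizes the objective (its sub-threshold tails are compared against
zeroed data), and the experiment would measure that support mismatch rather
than optimizer behaviour. Additionally,
raw surrogates (ADC maps via the exact inverse of the linear cellularity
map, DW signals at b = 150/500/1100 s/mm², DCE curves proportional to a
gamma-variate arterial input, pre/post-contrast volumes) exercise the
imaging-derivation operators, which invert them exactly in the noiseless
case.

What the phantoms do **not** emulate: registration error, spatially
correlated or Rician MRI noise, partial-volume effects at the brain
surface, necrotic-core heterogeneity beyond what the model itself produces,
and inter-subject anatomical variability. Passing recovery tests therefore
demonstrates the correctness and identifiability of the computational
pipeline under the model's own assumptions, not the biological fidelity of
the model to any particular dataset.

## Problem sizes and experiment design

The shipped experiments use desk-scale grids chosen so the full suite runs
in minutes while remaining 3D and anisotropic: 32 x 32 x 8 voxels at
1 x 1 x 2 mm (the full field of view, coarsened 4x in-plane) for the
parameter-recovery and forecast-closure experiments, and 16 x 16 x 8 for
the five-subject model-selection cohorts (2 subjects at 20 Gy, 3 at 40 Gy,
mirroring the study's dose split). Recovery calibrates
$\{k_{p,T}, k_{p,V}, k_{d,V}, D_{T,0}, \alpha_3\}$ from ±50% perturbed
initial guesses; selection calibrates four growth parameters plus each
coupling's own parameters with an iteration cap of 5, which is enough for
the AIC ordering to stabilize. Full-scale 128 x 128 x 16 runs use the same
code paths and remain single-workstation problems.

## Known limitations

- The forward scheme is first-order in time; the default $\Delta t$ keeps
  temporal error far below measurement noise, but stiff parameter regimes
  (very high $k_{p,T}$ or diffusivities) require a smaller step, enforced
  only through the CFL/update guards.
- The local-k_pV parameterization inflates $k$ quickly; with desk-scale
  masks the AIC correction term $n - k - 1$ stays comfortably positive, but
  tiny evaluation masks with local models may approach the pole and raise a
  validation error instead of returning a misleading AIC.
- Weakly identifiable directions (e.g. $k_{d,V}$ when the tumor interior is
  small) slow LM progress; the 0.5% stagnation rule can then stop early.
  The annealing component mitigates but does not eliminate this.
- Single-fraction schedules are the tested path; multi-fraction plans are
  accepted (the immediate effect is applied per event) but not exercised by
  the shipped experiments.
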