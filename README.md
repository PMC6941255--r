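# rtforecast

Image-driven forecasting of tumor and vasculature response to radiation
therapy.

`rtforecast` is for computational oncology groups who use quantitative MRI
to drive subject-specific tumor growth models. It implements a family of
ten mechanically-coupled reaction-diffusion models of the tumor cell volume
fraction φ_T and blood volume fraction φ_V on a 3D voxel grid — five
radiotherapy efficacy couplings crossed with global or locally calibrated
vascular proliferation — together with everything needed to run them
end-to-end: conversion of imaging surrogates (ADC maps, DCE time courses)
into volume-fraction maps, subject-specific calibration by a hybrid
simulated-annealing Levenberg–Marquardt scheme, corrected-AIC model
selection across the family, forward forecasting at held-out time points,
and global/voxelwise error analysis. A synthetic phantom generator
reproduces the study structure (7 imaging days, single-fraction 20 or
40 Gy whole-brain irradiation at day 14.5) so the entire pipeline runs
without any external data.

## The model in brief

Tumor cells diffuse and proliferate logistically against a
vascularity-dependent carrying capacity:

    ∂φ_T/∂t = ∇·(D_T ∇φ_T) + R_LT(t) k_pT φ_T (1 − (φ_T + φ_V)/θ_TV)

with D_T = D_T0 exp(−λ₁ σ_vm), where the von Mises stress σ_vm comes from a
linear-elastic equilibrium forced by tumor cell gradients (slip conditions
at the brain boundary). The vasculature grows by angiogenesis at the tumor
periphery and regresses in the interior, modulated by a normalized
distance-to-periphery field d:

    ∂φ_V/∂t = ∇·(D_V ∇φ_V) + R_LT,V(t) k_pV d φ_V (1 − φ_V/θ_V) − k_dV (1 − d) φ_V

Radiotherapy acts immediately (φ_post = φ_pre − α_I·C_I·φ_pre, on both
fields) and long-term (R_LT = α_LT·C_LT after the irradiation day). The
five couplings C1–C5 tie the efficacy fields C_I, C_LT to logistic
saturation, the linear-quadratic dose response (α/β = 14), local
vascularity, an oxygen enhancement ratio, or nothing (uniform). See the
methods vignette (`vignettes/forecasting-rt-response.Rmd`) for the full
treatment.

## Worked example

Generate a desk-scale phantom, calibrate the generating model on time
points 1–5, and score its forecast at the held-out days 20.5 and 22.5:

```r
library(rtforecast)

cfg  <- simulation_config(mechanics_cadence = 25)
spec <- phantom_spec(noise_sd = 0.01, sim_config = cfg)   # 32 x 32 x 8, C3, 40 Gy
ph   <- make_phantom(spec)
meas <- generate_measurements(ph, spec)

prob <- calibration_problem(
  meas$noisy, ph$grid, ph$mech, model_id = "C3_global",
  base_params = ph$truth$params, dose = 40, t_rt = 14.5,
  free = c("k_pT", "k_pV", "k_dV", "D_T0", "alpha3"),
  plan_args = list(alpha_I = 0.6, alpha_LT = 0.75),
  sim_config = cfg)

fit <- calibrate(prob, calibration_control(max_iter = 40), rng_seed = 7)
print(fit)
#> <calibration_result> C3_global: RSS = 0.678737 (k = 5, n = 4208, 4 iterations, converged)
#>   k_pT = 0.5742
#>   k_pV = 0.2302
#>   k_dV = 0.1363
#>   D_T0 = 0.08646
#>   alpha3 = 5.742

fc  <- forecast(fit, prob, c(20.5, 22.5))
rep <- evaluate_prediction(fc, meas$noisy, prob$params$theta_min, ph$grid)
print(as.data.frame(rep), digits = 3)
#>   time volume_pred_mm3 volume_meas_mm3 volume_percent_error  dice ccc_phiT
#> 1 20.5             482             388                 24.2 0.892    0.984
#> 2 22.5             614             460                 33.5 0.857    0.979
#>   ccc_phiV n_voxels
#> 1    0.772      241
#> 2    0.773      307
```

`fit` reports the estimated rates (1/day), diffusivity (mm²/day) and the
vascular coupling scale (generating values: 0.5, 0.25, 0.15, 0.05, 6), the
residual sum of squares over the ~4200 fitted voxel measurements, and the
calibrated parameter count used by the AIC. `rep` holds, per held-out day,
the signed percent error in thresholded tumor volume, the Dice overlap of
predicted and measured tumor masks, and the concordance correlation of each
field over their union — the same three statistics used to judge forecasts
throughout the package. The residual volume bias comes from forecasting off
a noisy measured initial map with data-assigned thresholds; with the truth
parameters on a noiseless phantom all three metrics are exact (0% volume
error, Dice 1, CCC 1).

Cohort-level selection across subjects and models is one call; on a
three-subject cohort generated from the vascular coupling it recovers the
generating model:

```r
res <- run_pipeline(subjects, models = c("C2_global", "C3_global", "C5_global"),
                    free = c("k_pT", "k_pV", "k_dV", "D_T0"),
                    control = calibration_control(max_iter = 5),
                    sim_config = cfg, rng_seed = 1)
res$selection
#> <selection_table> average rank (times ranked first):
#>   C3_global  1.00 (3)
#>   C5_global  2.00 (0)
#>   C2_global  3.00 (0)
#> selected: C3_global
```

A thin command-line wrapper with `synth`, `simulate` and `run` subcommands
is installed at `inst/cli/rtforecast.R`.

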