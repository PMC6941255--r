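# Shared fixtures: all built in code at test time.

tiny_grid <- function(dims = c(8, 7, 5), spacing = c(1, 1, 2)) {
  make_grid(dims, spacing, ellipsoid_mask(dims, spacing))
}

# random in-range fields on a grid, zero outside the brain
random_state <- function(grid, seed = 1, hiT = 0.5, hiV = 0.2) {
  set.seed(seed)
  phiT <- array(0, grid$dims)
  phiV <- array(0, grid$dims)
  nb <- sum(grid$brain_mask)
  phiT[grid$brain_mask] <- runif(nb, 0, hiT)
  phiV[grid$brain_mask] <- runif(nb, 0, hiV)
  list(phi_T = phiT, phi_V = phiV)
}

# the desk-scale study phantom used by the calibration experiments
desk_cfg <- function(cadence = 25) simulation_config(mechanics_cadence = cadence)

recovery_spec <- function(noise_sd = 0.01, ...) {
  # whole-brain additive noise (the idealized measurement model), so the
  # experiment isolates optimizer recovery from ROI-support effects
  phantom_spec(noise_sd = noise_sd, phiT_roi_only = FALSE,
               sim_config = desk_cfg(), ...)
}

# calibration problem for the parameter-recovery experiment: C3-global
# generating model, free {k_pT, k_pV, k_dV, D_T0, alpha3}, assigned
# quantities fixed at the generating values, truth initial condition with
# noisy fitted time points
recovery_problem <- function(ph, meas, spec) {
  truth <- ph$truth$params
  ser <- meas$noisy
  ser$phi_T[[1]] <- meas$truth$phi_T[[1]]
  ser$phi_V[[1]] <- meas$truth$phi_V[[1]]
  calibration_problem(
    ser, ph$grid, ph$mech, model_id = "C3_global",
    base_params = truth, dose = ph$truth$plan$dose, t_rt = ph$truth$plan$t_rt,
    free = c("k_pT", "k_pV", "k_dV", "D_T0", "alpha3"),
    plan_args = list(alpha_I = ph$truth$plan$alpha_I,
                     alpha_LT = ph$truth$plan$alpha_LT),
    assign = list(theta_min = truth$theta_min, theta_V = truth$theta_V,
                  tumor_threshold = spec$tumor_threshold),
    sim_config = spec$sim_config)
}

recovery_truth_values <- function(ph) {
  c(k_pT = ph$truth$params$k_pT, k_pV = ph$truth$params$k_pV,
    k_dV = ph$truth$params$k_dV, D_T0 = ph$truth$params$D_T0,
    alpha3 = ph$truth$plan$alpha3)
}

# compact cohort phantom for the model-selection experiment
cohort_spec <- function(dose, noise_sd = 0.01) {
  phantom_spec(dims = c(16, 16, 8), spacing = c(1, 1, 2),
               seed_center = c(9.5, 8.5, 7), seed_radius = 2.2,
               plan = radiotherapy_plan(dose = dose),
               noise_sd = noise_sd, sim_config = desk_cfg(), rng_seed = 1L)
}
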