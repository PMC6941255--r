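#' Simulation configuration
#'
#' Numerical knobs for the explicit time integrator. The default time step of
#' 0.01 days and central-difference space discretization follow the model's
#' reference numerics; the mechanics (and distance-field) refresh cadence is
#' a configurable operator-splitting choice: the elasticity solve dominates
#' cost while phi_T changes slowly per step, so sigma_vm is refreshed every
#' `mechanics_cadence` transport steps.
#'
#' @param dt time step in days (> 0), default 0.01.
#' @param mechanics_cadence transport steps between mechanics / distance
#'   field refreshes, default 10.
#' @param output_times days at which to snapshot the state (nearest completed
#'   step); defaults to the end of the simulated span.
#' @param stability_check abort on CFL >= 1 or an excessive single-step voxel
#'   update (`max_update`); if `FALSE`, warn instead.
#' @param max_update largest tolerated single-step voxel change.
#' @param recompute_CLT re-evaluate the long-term coupling field at every
#'   refresh after irradiation instead of freezing it at the irradiation
#'   instant (default `FALSE`: frozen, matching the piecewise-constant
#'   long-term factor).
#' @param tumor_threshold phi_T level defining the tumor mask used for the
#'   distance-to-periphery field; defaults to the subject's `theta_min`.
#' @param rng_seed reserved; the solver is deterministic.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 0.01, mechanics_cadence = 10,
                              output_times = NULL, stability_check = TRUE,
                              max_update = 0.25, recompute_CLT = FALSE,
                              tumor_threshold = NULL, rng_seed = NULL) {
  if (dt <= 0) validation_error("dt must be positive")
  if (mechanics_cadence < 1)
    validation_error("mechanics_cadence must be >= 1")
  structure(list(dt = dt, mechanics_cadence = as.integer(mechanics_cadence),
                 output_times = output_times,
                 stability_check = isTRUE(stability_check),
                 max_update = max_update,
                 recompute_CLT = isTRUE(recompute_CLT),
                 tumor_threshold = tumor_threshold, rng_seed = rng_seed),
            class = "simulation_config")
}

#' Explicit-diffusion stability (CFL) check
#'
#' Returns the CFL number `2 max(D) dt (1/dx^2 + 1/dy^2 + 1/dz^2)` of the
#' explicit scheme and a pass flag (fail if >= 1). Stress damping only ever
#' reduces D, so the undamped diffusivities bound the true CFL.
#'
#' @param params growth parameters (or a single diffusivity value).
#' @param grid the grid.
#' @param dt time step in days.
#' @return list with `cfl` and `pass`.
#' @export
check_stability <- function(params, grid, dt) {
  D <- if (inherits(params, "growth_parameters"))
    max(params$D_T0, params$D_V0) else max(params)
  cfl <- 2 * D * dt * sum(1 / grid$spacing^2)
  list(cfl = cfl, pass = cfl < 1)
}

# Internal: update damped diffusivity fields from the current phi_T.
refresh_mechanics <- function(phi_T, params, mech, grid) {
  if (mech$lambda1 > 0 || params$lambda1 > 0) {
    lam1 <- params$lambda1
    sol <- solve_displacement(phi_T, mech, grid)
    svm <- von_mises_stress(sol$u, mech, grid)
    list(D_T = damp_diffusion(params$D_T0, lam1, svm),
         D_V = damp_diffusion(params$D_V0, lam1, svm),
         sigma_vm = svm)
  } else {
    list(D_T = array(params$D_T0, grid$dims),
         D_V = array(params$D_V0, grid$dims),
         sigma_vm = array(0, grid$dims))
  }
}

#' Advance the coupled tumor / vasculature system
#'
#' Forward-Euler integration of the coupled reaction-diffusion system from a
#' single initial time point, with no-flux boundaries at the brain-mask
#' surface, mechanics-damped diffusivities refreshed on a configurable
#' cadence, and radiotherapy events: at the first step whose time reaches an
#' irradiation day, the coupling fields are evaluated from the current state,
#' the immediate reduction is applied to both species, and the long-term
#' factor multiplies the proliferation terms thereafter.
#'
#' @param initial a [field_series()] (its first time point is used) or a list
#'   with `phi_T`, `phi_V`, `time`.
#' @param params a [growth_parameters()].
#' @param plan a [radiotherapy_plan()], or `NULL` for untreated growth.
#' @param mech a [mechanical_state()].
#' @param grid the grid.
#' @param config a [simulation_config()]; `output_times` must be >= the
#'   initial time.
#' @return A [field_series()] at the requested output times, with tumor masks
#'   thresholded at the configured level and a `run_log` attribute (step
#'   count, CFL, floored-voxel count, RT events applied).
#' @export
simulate_growth <- function(initial, params, plan, mech, grid,
                            config = simulation_config()) {
  if (inherits(initial, "scalar_field_series")) {
    t0 <- initial$times[1]
    phiT <- initial$phi_T[[1]]
    phiV <- initial$phi_V[[1]]
  } else {
    t0 <- initial$time
    phiT <- initial$phi_T
    phiV <- initial$phi_V
  }
  bm <- grid$brain_mask
  phiT[!bm] <- 0
  phiV[!bm] <- 0
  dt <- config$dt
  out_times <- sort(config$output_times %||% (t0 + 1))
  if (any(out_times < t0 - 1e-9))
    validation_error("output_times must not precede the initial time")
  steps_out <- as.integer(round((out_times - t0) / dt))
  n_steps <- max(steps_out)

  stab <- check_stability(params, grid, dt)
  if (!stab$pass) {
    msg <- sprintf("explicit scheme unstable: CFL = %.3g >= 1", stab$cfl)
    if (config$stability_check) numerical_error(msg) else warning(msg)
  }

  # radiotherapy event steps: immediate effect precedes that step's update
  rt_steps <- integer(0)
  if (!is.null(plan)) {
    active <- plan$t_rt <= t0 + n_steps * dt + 1e-9
    rt_steps <- pmax(0L, as.integer(ceiling((plan$t_rt[active] - t0) / dt - 1e-9)))
    rt_dose <- plan$dose[active]
  }
  thr <- config$tumor_threshold %||% params$theta_min
  kpV_field <- if (length(params$k_pV) == 1) array(params$k_pV, grid$dims)
               else params$k_pV
  ones <- array(1, grid$dims)
  RLT_T <- ones
  RLT_V <- ones
  rt_applied <- logical(length(rt_steps))
  post_rt <- FALSE
  floor_total <- 0
  snaps <- vector("list", length(steps_out))

  breaks <- sort(unique(c(0L, steps_out, rt_steps, n_steps)))
  step <- 0L
  record <- function(s) {
    hits <- which(steps_out == s)
    for (hh in hits)
      snaps[[hh]] <<- list(phi_T = phiT, phi_V = phiV)
  }
  record(0L)

  for (bi in seq_along(breaks)[-1]) {
    target <- breaks[bi]
    # radiotherapy events at the start of this segment
    ev <- which(rt_steps == breaks[bi - 1] & !rt_applied)
    for (e in ev) {
      theta_T <- carrying_capacity(phiV, params)
      cpl <- compute_coupling(plan, phiT, phiV, theta_T, params$theta_V,
                              dose = rt_dose[e])
      phiT <- apply_immediate_effect(phiT, plan$alpha_I, cpl$C_I)
      phiV <- apply_immediate_effect(phiV, plan$alpha_I_V, cpl$C_I)
      RLT_T <- plan$alpha_LT * cpl$C_LT
      RLT_V <- RLT_T
      rt_applied[e] <- TRUE
      post_rt <- TRUE
      record(breaks[bi - 1])  # snapshots at the RT step see the post-RT state
    }
    while (step < target) {
      nsub <- min(config$mechanics_cadence, target - step)
      mechf <- refresh_mechanics(phiT, params, mech, grid)
      tum <- bm & (phiT >= thr)
      dfld <- if (any(tum)) distance_to_periphery(tum, grid)
              else array(0, grid$dims)
      if (post_rt && config$recompute_CLT) {
        theta_T <- carrying_capacity(phiV, params)
        cpl <- compute_coupling(plan, phiT, phiV, theta_T, params$theta_V)
        RLT_T <- plan$alpha_LT * cpl$C_LT
        RLT_V <- RLT_T
      }
      res <- cpp_advance(as.numeric(phiT), as.numeric(phiV),
                         as.numeric(mechf$D_T), as.numeric(mechf$D_V),
                         as.logical(bm), as.logical(tum),
                         as.numeric(dfld), as.numeric(kpV_field),
                         params$k_pT, params$k_dV,
                         params$theta_max, params$theta_min,
                         params$phiV_thresh, params$theta_V,
                         as.numeric(RLT_T), as.numeric(RLT_V),
                         grid$dims, grid$spacing, dt, as.integer(nsub))
      if (!res$ok)
        numerical_error("simulation aborted at step %d: %s", step, res$error)
      if (res$max_delta > config$max_update) {
        msg <- sprintf("step %d: voxel update %.3g exceeds bound %.3g",
                       step, res$max_delta, config$max_update)
        if (config$stability_check) numerical_error(msg) else warning(msg)
      }
      floor_total <- floor_total + res$floor_count
      phiT <- array(res$phi_T, grid$dims)
      phiV <- array(res$phi_V, grid$dims)
      step <- step + nsub
    }
    record(step)
  }
  # RT exactly at the final step (no transport after it)
  ev <- which(rt_steps == n_steps & !rt_applied)
  for (e in ev) {
    theta_T <- carrying_capacity(phiV, params)
    cpl <- compute_coupling(plan, phiT, phiV, theta_T, params$theta_V,
                            dose = rt_dose[e])
    phiT <- apply_immediate_effect(phiT, plan$alpha_I, cpl$C_I)
    phiV <- apply_immediate_effect(phiV, plan$alpha_I_V, cpl$C_I)
    rt_applied[e] <- TRUE
    record(n_steps)
  }

  out <- field_series(
    times = out_times,
    phi_T = lapply(snaps, `[[`, "phi_T"),
    phi_V = lapply(snaps, `[[`, "phi_V"),
    tumor_masks = lapply(snaps, function(s) bm & (s$phi_T >= thr)))
  attr(out, "run_log") <- list(steps = n_steps, dt = dt, cfl = stab$cfl,
                               floor_events = floor_total,
                               rt_events = sum(rt_applied),
                               tumor_threshold = thr)
  out
}
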