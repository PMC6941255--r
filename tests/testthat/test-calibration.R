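# a tiny, fast calibration setup shared across the blocks below
tiny_problem <- function(noise_sd = 0, free = c("k_pT", "alpha3"),
                         truth_ic = TRUE) {
  cfg <- simulation_config(mechanics_cadence = 25)
  spec <- phantom_spec(dims = c(12, 12, 6), spacing = c(1.5, 1.5, 2),
                       seed_radius = 2.5, noise_sd = noise_sd,
                       sim_config = cfg, rng_seed = 2L)
  ph <- make_phantom(spec)
  meas <- generate_measurements(ph, spec)
  ser <- meas$noisy
  if (truth_ic) {
    ser$phi_T[[1]] <- meas$truth$phi_T[[1]]
    ser$phi_V[[1]] <- meas$truth$phi_V[[1]]
  }
  truth <- ph$truth$params
  prob <- calibration_problem(
    ser, ph$grid, ph$mech, model_id = "C3_global",
    base_params = truth, dose = spec$plan$dose, t_rt = spec$plan$t_rt,
    free = free,
    plan_args = list(alpha_I = spec$plan$alpha_I,
                     alpha_LT = spec$plan$alpha_LT,
                     alpha3 = spec$plan$alpha3),
    assign = list(theta_min = truth$theta_min, theta_V = truth$theta_V,
                  tumor_threshold = spec$tumor_threshold),
    sim_config = cfg)
  list(prob = prob, ph = ph, spec = spec, meas = meas)
}

test_that("the objective vanishes at the generating truth and detects perturbation", {
  tp <- tiny_problem(noise_sd = 0)
  truth_par <- list(k_pT = tp$ph$truth$params$k_pT,
                    alpha3 = tp$ph$truth$plan$alpha3)
  sse0 <- objective(truth_par, tp$prob)
  expect_lt(sse0, 1e-18)
  sse1 <- objective(list(k_pT = truth_par$k_pT * 1.2,
                         alpha3 = truth_par$alpha3), tp$prob)
  expect_gt(sse1, 1e-4)
  # unknown parameter names are refused
  expect_error(objective(list(bogus = 1), tp$prob),
               class = "rtforecast_validation_error")
})

test_that("noise raises the objective floor to about n sigma^2", {
  tp <- tiny_problem(noise_sd = 0.01)
  truth_par <- list(k_pT = tp$ph$truth$params$k_pT,
                    alpha3 = tp$ph$truth$plan$alpha3)
  sse <- objective(truth_par, tp$prob)
  n <- length(rtforecast:::problem_residuals(tp$prob, tp$prob$theta0))
  # chi-square expectation; generous band (truncation removes some mass)
  expect_gt(sse, 0.5 * n * 0.01^2)
  expect_lt(sse, 2.0 * n * 0.01^2)
})

test_that("the hybrid optimizer honours caps, seeds and monotone best-so-far", {
  tp <- tiny_problem(noise_sd = 0)
  init <- list(k_pT = tp$ph$truth$params$k_pT * 1.7,
               alpha3 = tp$ph$truth$plan$alpha3 * 0.6)
  # iteration cap of 1: returns after one iteration, not converged
  f1 <- calibrate(tp$prob, calibration_control(max_iter = 1), rng_seed = 3,
                  init = init)
  expect_identical(f1$iterations, 1L)
  expect_false(f1$converged)
  # seeded determinism
  f2 <- calibrate(tp$prob, calibration_control(max_iter = 5), rng_seed = 3,
                  init = init)
  f3 <- calibrate(tp$prob, calibration_control(max_iter = 5), rng_seed = 3,
                  init = init)
  expect_identical(f2$estimate, f3$estimate)
  expect_identical(f2$trajectory, f3$trajectory)
  # best-seen SSE along the trajectory is non-increasing
  expect_true(all(diff(cummin(f2$trajectory)) <= 0))
  expect_equal(f2$RSS, min(f2$trajectory))
  # truth as initial guess: immediate convergence with SSE ~ 0
  f4 <- calibrate(tp$prob, calibration_control(max_iter = 10), rng_seed = 1,
                  init = list(k_pT = tp$ph$truth$params$k_pT,
                              alpha3 = tp$ph$truth$plan$alpha3))
  expect_true(f4$converged)
  expect_lte(f4$iterations, 2L)
  expect_lt(f4$RSS, 1e-12)
})

test_that("local k_pV fields expand by the nearest-calibrated-site rule", {
  g <- make_grid(c(5, 5, 1), c(1, 1, 1))
  m <- array(FALSE, c(5, 5, 1)); m[2:4, 2:4, 1] <- TRUE
  lay <- rtforecast:::local_site_layout(m, g)
  expect_length(lay$sites, 5)   # four corners + centre
  # constant coarse values expand to a constant field
  fc <- expand_local_field(rep(7, 5), m, g, background = 1)
  expect_true(all(fc[m] == 7) && all(fc[!m] == 1))
  # distinct corners: edge midpoints take their nearest site (ties broken
  # by site order: corners column-major, then centre)
  f <- expand_local_field(c(10, 20, 30, 40, 50), m, g, background = 0)
  expect_equal(f[2:4, 2:4, 1],
               matrix(c(10, 10, 20, 10, 50, 20, 30, 30, 40), nrow = 3))
  # mask smaller than one block: every voxel calibrated directly
  m2 <- array(FALSE, c(5, 5, 1)); m2[2:3, 2:3, 1] <- TRUE
  lay2 <- rtforecast:::local_site_layout(m2, g)
  expect_length(lay2$sites, 4)
  f2 <- expand_local_field(1:4, m2, g, background = 0, layout = lay2)
  expect_equal(sort(f2[m2]), 1:4)
  expect_error(expand_local_field(1:3, m, g),
               class = "rtforecast_validation_error")
  expect_error(rtforecast:::local_site_layout(array(FALSE, c(5, 5, 1)), g),
               class = "rtforecast_validation_error")
})

test_that("a local model calibrates one scalar per coarse site", {
  cfg <- simulation_config(mechanics_cadence = 25)
  spec <- phantom_spec(dims = c(12, 12, 6), spacing = c(1.5, 1.5, 2),
                       noise_sd = 0, sim_config = cfg)
  ph <- make_phantom(spec)
  meas <- generate_measurements(ph, spec)
  prob <- calibration_problem(meas$noisy, ph$grid, ph$mech,
                              model_id = "C3_local",
                              base_params = ph$truth$params,
                              dose = 40, t_rt = 14.5,
                              free = c("k_pV", "alpha3"),
                              plan_args = list(alpha_I = 0.6, alpha_LT = 0.75),
                              sim_config = cfg)
  m <- length(prob$layout$sites)
  expect_gt(m, 1)
  expect_length(prob$theta0, m + 1)
  fit <- calibrate(prob, calibration_control(max_iter = 1), rng_seed = 1)
  expect_identical(fit$k, m + 1L)
  expect_length(grep("^k_pV_", names(fit$estimate)), m)
})
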