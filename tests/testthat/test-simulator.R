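frozen_ic <- function(g, vT = 0.2, vV = 0.1) {
  phiT <- array(0, g$dims); phiT[g$brain_mask] <- vT
  phiV <- array(0, g$dims); phiV[g$brain_mask] <- vV
  list(phi_T = phiT, phi_V = phiV, time = 0)
}

test_that("frozen dynamics reproduce the initial state exactly", {
  g <- tiny_grid(c(8, 8, 4))
  p <- growth_parameters(D_T0 = 0, D_V0 = 0, k_pT = 0, k_pV = 0, k_dV = 0,
                         lambda1 = 0)
  mech <- mechanical_state(g, lambda1 = 0)
  plan <- radiotherapy_plan(dose = 40, t_rt = 1, coupling = "C5_none",
                            alpha_I = 0, alpha_LT = 1)
  ic <- frozen_ic(g)
  sim <- simulate_growth(ic, p, plan, mech, g,
                         simulation_config(output_times = c(1, 2),
                                           tumor_threshold = 0.05))
  expect_identical(sim$phi_T[[1]], ic$phi_T)
  expect_identical(sim$phi_T[[2]], ic$phi_T)
  expect_identical(sim$phi_V[[2]], ic$phi_V)
})

test_that("zero-diffusion growth matches the analytic logistic solution", {
  g <- make_grid(c(6, 6, 4), c(1, 1, 1))
  p <- growth_parameters(D_T0 = 0, D_V0 = 0, k_pT = 0.5, k_pV = 0, k_dV = 0,
                         lambda1 = 0, phiV_thresh = 0.05, theta_max = 0.8,
                         theta_min = 0.1, theta_V = 0.2)
  set.seed(21)
  phi0 <- array(runif(prod(g$dims), 0.05, 0.3), g$dims)
  ic <- list(phi_T = phi0, phi_V = array(0.1, g$dims), time = 0)
  mech <- mechanical_state(g, lambda1 = 0)
  sim <- simulate_growth(ic, p, NULL, mech, g,
                         simulation_config(output_times = 10,
                                           tumor_threshold = 0.95))
  # dphi/dt = k phi (1 - (phi + c)/theta): logistic toward A = theta - c
  theta <- 0.8 + 0.2; k <- 0.5; c0 <- 0.1; A <- theta - c0; t <- 10
  closed <- A * phi0 / (phi0 + (A - phi0) * exp(-k * A * t / theta))
  expect_lt(max(abs(sim$phi_T[[1]] - closed) / closed), 1e-3)
})

test_that("pure diffusion conserves mass under no-flux boundaries", {
  g <- tiny_grid(c(10, 10, 6))
  p <- growth_parameters(D_T0 = 0.2, D_V0 = 0.1, k_pT = 0, k_pV = 0,
                         k_dV = 0, lambda1 = 0)
  set.seed(22)
  phiT0 <- array(0, g$dims); phiT0[5, 5, 3] <- 0.8
  phiV0 <- array(0, g$dims)
  phiV0[g$brain_mask] <- runif(sum(g$brain_mask), 0, 0.2)
  mech <- mechanical_state(g, lambda1 = 0)
  # 1000 steps of dt = 0.01
  sim <- simulate_growth(list(phi_T = phiT0, phi_V = phiV0, time = 0), p,
                         NULL, mech, g,
                         simulation_config(output_times = 10,
                                           tumor_threshold = 0.99))
  expect_lt(abs(sum(sim$phi_T[[1]]) - sum(phiT0)) / sum(phiT0), 1e-10)
  expect_lt(abs(sum(sim$phi_V[[1]]) - sum(phiV0)) / sum(phiV0), 1e-10)
})

test_that("the solver is deterministic and a zero-dose LQ event is inert", {
  g <- tiny_grid(c(8, 8, 4))
  p <- growth_parameters(lambda1 = 0)
  mech <- mechanical_state(g, lambda1 = 0)
  ic <- frozen_ic(g, 0.25, 0.12)
  cfg <- simulation_config(output_times = c(1, 2), tumor_threshold = 0.05)
  s1 <- simulate_growth(ic, p, NULL, mech, g, cfg)
  s2 <- simulate_growth(ic, p, NULL, mech, g, cfg)
  expect_identical(s1$phi_T, s2$phi_T)
  expect_identical(s1$phi_V, s2$phi_V)
  plan0 <- radiotherapy_plan(dose = 0, t_rt = 1, coupling = "C2_LQ",
                             alpha = 0.05)
  s3 <- simulate_growth(ic, p, plan0, mech, g, cfg)
  expect_identical(s3$phi_T, s1$phi_T)
  expect_identical(s3$phi_V, s1$phi_V)
})

test_that("halving dt changes the logistic solution within first-order error", {
  g <- make_grid(c(4, 4, 2), c(1, 1, 1))
  p <- growth_parameters(D_T0 = 0, D_V0 = 0, k_pT = 0.5, k_pV = 0, k_dV = 0,
                         lambda1 = 0, phiV_thresh = 0.05, theta_max = 0.8,
                         theta_min = 0.1, theta_V = 0.2)
  ic <- list(phi_T = array(0.1, g$dims), phi_V = array(0.1, g$dims), time = 0)
  mech <- mechanical_state(g, lambda1 = 0)
  run <- function(dt) simulate_growth(ic, p, NULL, mech, g,
    simulation_config(dt = dt, output_times = 10, tumor_threshold = 0.95))
  a <- run(0.01)$phi_T[[1]][1]
  b <- run(0.005)$phi_T[[1]][1]
  theta <- 1; k <- 0.5; A <- 0.9; t <- 10
  exact <- A * 0.1 / (0.1 + (A - 0.1) * exp(-k * A * t / theta))
  # forward Euler: error scales ~ dt
  expect_lt(abs(b - exact), abs(a - exact))
  expect_lt(abs(a - exact) / exact, 2e-3)
})

test_that("stability check reports the explicit-diffusion CFL number", {
  g <- make_grid(c(8, 8, 4), c(0.25, 0.25, 1))
  expect_equal(check_stability(growth_parameters(D_T0 = 0, D_V0 = 0), g, 0.01)$cfl, 0)
  coef <- 2 * 0.01 * sum(1 / g$spacing^2)
  D_half <- 0.5 / coef
  cs <- check_stability(D_half, g, 0.01)
  expect_equal(cs$cfl, 0.5)
  expect_true(cs$pass)
  cs2 <- check_stability(1.5 / coef, g, 0.01)
  expect_equal(cs2$cfl, 1.5)
  expect_false(cs2$pass)
  # the simulator refuses an unstable configuration
  p_bad <- growth_parameters(D_T0 = 2 / coef, lambda1 = 0)
  mech <- mechanical_state(g, lambda1 = 0)
  ic <- list(phi_T = array(0.1, g$dims), phi_V = array(0.1, g$dims), time = 0)
  expect_error(simulate_growth(ic, p_bad, NULL, mech, g,
                               simulation_config(output_times = 1,
                                                 tumor_threshold = 0.05)),
               class = "rtforecast_numerical_error")
})
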