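# dense brute-force solve of the assembled operator (the independent oracle)
dense_solve_displacement <- function(phi, mech, grid) {
  sys <- rtforecast:::assemble_elasticity(mech, grid)
  b <- c(as.numeric(sys$Dc[[1]] %*% phi[sys$idx]),
         as.numeric(sys$Dc[[2]] %*% phi[sys$idx]),
         as.numeric(sys$Dc[[3]] %*% phi[sys$idx])) * (-mech$lambda2)
  b[sys$bc_rows] <- 0
  list(u = solve(as.matrix(sys$A), b), sys = sys, b = b)
}

pack_u <- function(u, sys) {
  c(u[, , , 1][sys$idx], u[, , , 2][sys$idx], u[, , , 3][sys$idx])
}

test_that("displacement matches a dense direct solve of the same operator", {
  # 1D two-compartment phantom
  g1 <- make_grid(c(8, 1, 1), c(0.25, 0.25, 1))
  m1 <- mechanical_state(g1, lambda1 = 1e-3)
  phi <- array(0, c(8, 1, 1)); phi[5:8, , ] <- 0.5
  oracle <- dense_solve_displacement(phi, m1, g1)
  sol <- solve_displacement(phi, m1, g1)
  expect_lt(max(abs(pack_u(sol$u, oracle$sys) - oracle$u)) / max(abs(oracle$u)),
            1e-10)

  # anisotropic 3D phantom under 10^3 voxels
  g2 <- tiny_grid(c(7, 6, 5), c(0.3, 0.4, 0.5))
  m2 <- mechanical_state(g2, G = 2100, nu = 0.45, lambda1 = 1e-3)
  set.seed(4)
  phi2 <- array(0, g2$dims)
  phi2[g2$brain_mask] <- runif(sum(g2$brain_mask), 0, 0.6)
  oracle2 <- dense_solve_displacement(phi2, m2, g2)
  sol2 <- solve_displacement(phi2, m2, g2)
  expect_lt(max(abs(pack_u(sol2$u, oracle2$sys) - oracle2$u)) /
              max(abs(oracle2$u)), 1e-10)
  # equilibrium residual contract
  expect_lt(sol2$residual, 1e-8)
})

test_that("zero forcing and linearity of the mechanics", {
  g <- tiny_grid(c(7, 6, 5))
  m <- mechanical_state(g, lambda1 = 1e-3)
  # spatially uniform phi_T: zero gradient, u = 0 exactly
  sol_u <- solve_displacement(array(0.4, g$dims), m, g)
  expect_identical(max(abs(sol_u$u)), 0)
  expect_identical(max(von_mises_stress(sol_u$u, m, g)), 0)
  # lambda2 = 0: zero forcing
  m0 <- mechanical_state(g, lambda1 = 1e-3, lambda2 = 0)
  st <- random_state(g, seed = 5)
  expect_identical(max(abs(solve_displacement(st$phi_T, m0, g)$u)), 0)
  # linearity in the forcing
  s1 <- solve_displacement(st$phi_T, m, g)
  s2 <- solve_displacement(3 * st$phi_T, m, g)
  expect_equal(s2$u, 3 * s1$u, tolerance = 1e-12)
})

test_that("von Mises stress follows the deviatoric stress tensor", {
  g <- make_grid(c(6, 6, 6), c(1, 1, 1))
  m <- mechanical_state(g)  # G = 2100, nu = 0.45
  xyz <- rtforecast:::voxel_coords(g)
  # pure hydrostatic strain u = c * x: deviatoric part vanishes (interior)
  uh <- array(0, c(g$dims, 3))
  for (k in 1:3) uh[, , , k] <- array(0.01 * xyz[, k], g$dims)
  vmh <- von_mises_stress(uh, m, g)
  expect_equal(max(abs(vmh[2:5, 2:5, 2:5])), 0)
  # uniaxial strain eps_xx = 0.01: hand-evaluated tensor algebra
  uu <- array(0, c(g$dims, 3))
  uu[, , , 1] <- array(0.01 * xyz[, 1], g$dims)
  vmu <- von_mises_stress(uu, m, g)
  G <- 2100; nu <- 0.45; lam <- 2 * G * nu / (1 - 2 * nu); eps <- 0.01
  s11 <- (2 * G + lam) * eps; s22 <- lam * eps
  vm_hand <- sqrt(0.5 * ((s11 - s22)^2 + (s11 - s22)^2))  # s22 = s33
  expect_equal(vmu[3, 3, 3], vm_hand, tolerance = 1e-12)
  expect_true(all(vmu >= 0))
})

test_that("stress damping is exponential, bounded and monotone", {
  svm <- array(c(0, 100, 500, log(2) / 1e-3), c(2, 2, 1))
  expect_equal(damp_diffusion(0.1, 0, svm), array(0.1, c(2, 2, 1)))
  expect_equal(damp_diffusion(0.1, 1e-3, array(0, c(2, 2, 1))),
               array(0.1, c(2, 2, 1)))
  D <- damp_diffusion(0.1, 1e-3, svm)
  expect_equal(D[2, 2, 1], 0.05)  # lambda1 * sigma = ln 2 halves D
  expect_true(all(D <= 0.1 & D > 0))
  # pointwise monotone: larger stress never increases D
  expect_true(all(diff(as.numeric(D)[order(as.numeric(svm))]) <= 0))
  expect_error(damp_diffusion(-1, 0, svm), class = "rtforecast_validation_error")
  expect_error(damp_diffusion(0.1, -1, svm), class = "rtforecast_validation_error")
})

test_that("near-incompressible Poisson ratio is rejected", {
  g <- tiny_grid(c(5, 5, 4))
  expect_error(mechanical_state(g, nu = 0.5),
               class = "rtforecast_validation_error")
  expect_error(mechanical_state(g, nu = 0.7),
               class = "rtforecast_validation_error")
})
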