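shift3 <- rtforecast:::shift3

test_that("carrying capacity is piecewise linear, continuous and monotone", {
  p <- growth_parameters(phiV_thresh = 0.1, theta_max = 0.8, theta_min = 0.2)
  expect_equal(carrying_capacity(0.1, p), 0.8)      # both branches agree
  expect_equal(carrying_capacity(0.25, p), 0.8)     # above threshold
  expect_equal(carrying_capacity(0, p), 0.2)        # linear branch at zero
  expect_equal(carrying_capacity(0.05, p), 0.5)     # linear midpoint
  # continuity at the threshold and monotonicity
  pv <- seq(0, 0.3, by = 1e-3)
  th <- carrying_capacity(pv, p)
  expect_true(all(diff(th) >= 0))
  expect_lt(max(abs(diff(th))), 1e-2)
  expect_error(growth_parameters(phiV_thresh = 0),
               class = "rtforecast_validation_error")
})

test_that("distance to periphery is physical, normalized and exact", {
  g <- make_grid(c(11, 11, 7), c(1, 1, 2))
  # solid ball mask (radius in mm)
  xyz <- rtforecast:::voxel_coords(g)
  ctr <- (g$dims - 1) / 2 * g$spacing
  r <- sqrt(colSums((t(xyz) - ctr)^2))
  ball <- array(r <= 4, g$dims)
  d <- distance_to_periphery(ball, g)
  # voxels with an in-plane non-tumor face neighbour sit at the minimal
  # physical distance (1 mm here), hence on the periphery with d = 1
  edge <- ball & !(
    shift3(ball, 1, 1, FALSE) & shift3(ball, 1, -1, FALSE) &
    shift3(ball, 2, 1, FALSE) & shift3(ball, 2, -1, FALSE))
  expect_true(all(d[edge] == 1))
  # unique deepest voxel at d = 0
  expect_equal(d[6, 6, 4], 0)
  expect_true(all(d[ball] >= 0 & d[ball] <= 1))
  expect_true(all(d[!ball] == 0))

  # single voxel: degenerate, all periphery
  single <- array(FALSE, g$dims); single[3, 3, 3] <- TRUE
  expect_equal(max(distance_to_periphery(single, g)), 1)
  expect_error(distance_to_periphery(array(FALSE, g$dims), g),
               class = "rtforecast_validation_error")

  # exactness of the anisotropic transform against brute force
  set.seed(11)
  m <- array(runif(8 * 7 * 5) < 0.4, c(8, 7, 5))
  m[1, 1, 1] <- FALSE  # keep background nonempty
  gm <- make_grid(c(8, 7, 5), c(0.7, 1.1, 2.0))
  dist <- array(rtforecast:::cpp_edt(as.logical(m), gm$dims, gm$spacing),
                gm$dims)
  co <- rtforecast:::voxel_coords(gm)
  bg <- which(!m)
  brute <- vapply(seq_along(m), function(v) {
    if (!m[v]) return(0)
    min(sqrt((co[bg, 1] - co[v, 1])^2 + (co[bg, 2] - co[v, 2])^2 +
               (co[bg, 3] - co[v, 3])^2))
  }, numeric(1))
  expect_equal(as.numeric(dist), brute, tolerance = 1e-12)

  # translation invariance
  m1 <- array(FALSE, c(10, 10, 6)); m1[3:5, 3:5, 2:3] <- TRUE
  m2 <- array(FALSE, c(10, 10, 6)); m2[6:8, 5:7, 3:4] <- TRUE
  gt <- make_grid(c(10, 10, 6), c(1, 1, 2))
  d1 <- distance_to_periphery(m1, gt)
  d2 <- distance_to_periphery(m2, gt)
  expect_equal(sort(d1[m1]), sort(d2[m2]))
})

test_that("tumor RHS combines conservative diffusion and logistic growth", {
  g <- tiny_grid(c(8, 7, 5))
  p <- growth_parameters(phiV_thresh = 0.05)
  # uniform state at combined capacity: rhs = 0
  phiV <- array(0, g$dims); phiV[g$brain_mask] <- 0.1
  thT <- carrying_capacity(0.1, p)
  phiT <- array(0, g$dims); phiT[g$brain_mask] <- thT + p$theta_V - 0.1
  der <- derived_fields(phiV, array(FALSE, g$dims), p, g)
  r <- tumor_rhs(phiT, phiV, array(0.1, g$dims), p, der, 1, g)
  expect_lt(max(abs(r)), 1e-12)
  # k_pT = 0, uniform phi_T: rhs = 0
  p0 <- growth_parameters(k_pT = 0)
  u <- array(0, g$dims); u[g$brain_mask] <- 0.3
  r0 <- tumor_rhs(u, phiV, array(0.1, g$dims), p0,
                  derived_fields(phiV, array(FALSE, g$dims), p0, g), 1, g)
  expect_lt(max(abs(r0)), 1e-12)

  # single interior voxel perturbation, uniform D: 7-point stencil by hand
  g4 <- make_grid(c(5, 5, 5), c(1, 1, 2))
  p4 <- growth_parameters(D_T0 = 0.1, k_pT = 0, lambda1 = 0)
  ph4 <- array(0.2, g4$dims); ph4[3, 3, 3] <- 0.3
  der4 <- derived_fields(array(0.2, g4$dims), array(FALSE, g4$dims), p4, g4)
  r4 <- tumor_rhs(ph4, array(0.2, g4$dims), array(0.1, g4$dims), p4, der4, 1, g4)
  expect_equal(r4[3, 3, 3],
               0.1 * (2 * (0.2 - 0.3) / 1 + 2 * (0.2 - 0.3) / 1 +
                        2 * (0.2 - 0.3) / 4))
  expect_equal(r4[2, 3, 3], 0.1 * (0.3 - 0.2) / 1)

  # zero capacity under positive phi_T is a numerical error
  pz <- growth_parameters(theta_min = 1e-3, theta_V = 1e-3, phiV_thresh = 1e-3)
  derz <- derived_fields(array(0, g4$dims), array(FALSE, g4$dims), pz, g4)
  derz$theta_TV <- array(0, g4$dims)
  expect_error(tumor_rhs(ph4, array(0, g4$dims), array(0, g4$dims), pz, derz, 1, g4),
               class = "rtforecast_numerical_error")
})

test_that("vascular RHS places angiogenesis at the periphery and death at depth", {
  g <- tiny_grid(c(8, 7, 5))
  p <- growth_parameters(k_pV = 0.3, k_dV = 0.2, theta_V = 0.2)
  tum <- array(FALSE, g$dims)
  tum[4:5, 3:5, 2:4] <- TRUE
  tum <- tum & g$brain_mask
  der <- derived_fields(array(0.1, g$dims), tum, p, g)

  # phi_V = theta_V uniform, d = 1 everywhere in tumor: rhs = 0
  der1 <- der; der1$d[tum] <- 1
  phiV <- array(0, g$dims); phiV[g$brain_mask] <- p$theta_V
  r <- vascular_rhs(phiV, phiV, array(0, g$dims), p, der1, 1, g)
  expect_lt(max(abs(r)), 1e-12)

  # rates zero, uniform phi_V: rhs = 0
  p0 <- growth_parameters(k_pV = 0, k_dV = 0)
  r0 <- vascular_rhs(phiV, phiV, array(0, g$dims), p0, der, 1, g)
  expect_lt(max(abs(r0)), 1e-12)

  # d = 0 at a tumor voxel, diffusion off: pure death -k_dV * phi_V
  v <- which(tum)[1]
  der0 <- der; der0$d[v] <- 0
  pv <- array(0, g$dims); pv[g$brain_mask] <- 0.1
  rv <- vascular_rhs(pv, pv, array(0, g$dims), p, der0, 1, g)
  expect_equal(rv[v], -p$k_dV * 0.1)

  # outside the tumor: no reaction terms (diffusion off -> rhs = 0)
  out <- g$brain_mask & !tum
  expect_true(all(rv[out] == 0))
})

test_that("compiled stepper matches the R right-hand sides for one step", {
  g <- tiny_grid(c(8, 7, 5))
  p <- growth_parameters()
  st <- random_state(g, seed = 2)
  tum <- g$brain_mask & st$phi_T >= 0.2
  DT <- array(0.05, g$dims); DV <- array(0.02, g$dims)
  der <- derived_fields(st$phi_V, tum, p, g)
  rT <- tumor_rhs(st$phi_T, st$phi_V, DT, p, der, 1, g)
  rV <- vascular_rhs(st$phi_V, st$phi_T, DV, p, der, 1, g)
  res <- rtforecast:::cpp_advance(
    as.numeric(st$phi_T), as.numeric(st$phi_V), as.numeric(DT), as.numeric(DV),
    as.logical(g$brain_mask), as.logical(tum), as.numeric(der$d),
    as.numeric(array(p$k_pV, g$dims)), p$k_pT, p$k_dV,
    p$theta_max, p$theta_min, p$phiV_thresh, p$theta_V,
    as.numeric(array(1, g$dims)), as.numeric(array(1, g$dims)),
    g$dims, g$spacing, 0.01, 1L)
  expect_equal(array(res$phi_T, g$dims), st$phi_T + 0.01 * rT, tolerance = 1e-14)
  expect_equal(array(res$phi_V, g$dims), st$phi_V + 0.01 * rV, tolerance = 1e-14)
})
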