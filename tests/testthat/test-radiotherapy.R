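mk_fields <- function(seed = 3, d = c(4, 4, 2)) {
  set.seed(seed)
  list(phiT = array(runif(prod(d), 0, 0.5), d),
       phiV = array(runif(prod(d), 0, 0.2), d),
       thT = array(0.8, d), d = d)
}

test_that("the five couplings reproduce their closed forms", {
  f <- mk_fields()
  # C5: uniform full efficacy
  c5 <- compute_coupling(radiotherapy_plan(coupling = "C5_none",
                                           alpha_I = 0.6, alpha_LT = 0.75),
                         f$phiT, f$phiV, f$thT, 0.22)
  expect_true(all(c5$C_I == 1) && all(c5$C_LT == 1))
  # C2 at dose 0: no immediate effect
  p2 <- radiotherapy_plan(coupling = "C2_LQ", dose = 0, alpha = 0.05)
  c2 <- compute_coupling(p2, f$phiT, f$phiV, f$thT, 0.22)
  expect_true(all(c2$C_I == 0) && all(c2$C_LT == 1))
  # C2/C4 parameter roles: alpha_I = alpha_LT = 1 and beta = alpha / 14
  expect_equal(p2$alpha_I, 1)
  expect_equal(p2$alpha_LT, 1)
  expect_equal(p2$beta, 0.05 / 14)
  # C3 at phi_V = theta_V: fully radiosensitive
  pv <- f$phiV; pv[1, 1, 1] <- 0.22
  c3 <- compute_coupling(radiotherapy_plan(coupling = "C3_vascular",
                                           alpha3 = 5, alpha_I = 0.5,
                                           alpha_LT = 0.5),
                         f$phiT, pv, f$thT, 0.22)
  expect_equal(c3$C_I[1, 1, 1], 1)
  expect_equal(c3$C_LT[1, 1, 1], 0)
  expect_equal(c3$C_LT, 1 - c3$C_I)
  # C4 with phi_V equal to the pre-treatment mean: OER = 1, reduces to C2
  p4 <- radiotherapy_plan(coupling = "C4_OER", dose = 20, alpha = 0.08,
                          phiV_pretreatment_mean = 0.1)
  c4 <- compute_coupling(p4, f$phiT, array(0.1, f$d), f$thT, 0.22)
  c2b <- compute_coupling(radiotherapy_plan(coupling = "C2_LQ", dose = 20,
                                            alpha = 0.08),
                          f$phiT, f$phiV, f$thT, 0.22)
  expect_true(all(c4$OER == 1))
  expect_equal(c4$C_I, c2b$C_I, tolerance = 1e-15)
  # C1 at saturation: radio-insensitive
  c1 <- compute_coupling(radiotherapy_plan(coupling = "C1_logistic",
                                           alpha_I = 0.5, alpha_LT = 0.5),
                         f$thT, f$phiV, f$thT, 0.22)
  expect_true(all(c1$C_I == 0))
})

test_that("immediate effect is a bounded direct reduction", {
  expect_equal(apply_immediate_effect(0.6, 0.5, 0.4), 0.48)   # Eq-6 arithmetic
  expect_equal(apply_immediate_effect(0.6, 1, 1), 0)          # complete kill
  expect_equal(apply_immediate_effect(0.6, 0, 1), 0.6)        # no effect
  f <- mk_fields(6)
  post <- apply_immediate_effect(f$phiT, 0.7, array(0.5, f$d))
  expect_true(all(post <= f$phiT) && all(post >= 0))
  z <- f$phiT; z[1, , ] <- 0
  expect_true(all(apply_immediate_effect(z, 0.9, array(1, f$d))[1, , ] == 0))
  expect_error(apply_immediate_effect(f$phiT, 1, array(1.5, f$d)),
               class = "rtforecast_validation_error")
})

test_that("long-term factor is piecewise in time", {
  p <- radiotherapy_plan(coupling = "C5_none", t_rt = 14.5,
                         alpha_I = 0.5, alpha_LT = 1)
  expect_identical(long_term_factor(14, p, array(1, c(2, 2, 1))), 1)
  expect_equal(long_term_factor(14.5, p, array(1, c(2, 2, 1))),
               array(1, c(2, 2, 1)))
  p2 <- radiotherapy_plan(coupling = "C5_none", t_rt = 14.5,
                          alpha_I = 0.5, alpha_LT = 0.5)
  expect_equal(long_term_factor(15, p2, array(0.8, c(2, 2, 1))),
               array(0.4, c(2, 2, 1)))
})

test_that("radiobiological monotonicities hold", {
  f <- mk_fields(8)
  doses <- c(5, 10, 20, 40, 80)
  ci2 <- vapply(doses, function(D)
    compute_coupling(radiotherapy_plan(coupling = "C2_LQ", dose = D,
                                       alpha = 0.05),
                     f$phiT, f$phiV, f$thT, 0.22)$C_I[1, 1, 1], numeric(1))
  expect_true(all(diff(ci2) > 0))
  ci4 <- vapply(doses, function(D)
    compute_coupling(radiotherapy_plan(coupling = "C4_OER", dose = D,
                                       alpha = 0.05,
                                       phiV_pretreatment_mean = 0.1),
                     f$phiT, array(0.15, f$d), f$thT, 0.22)$C_I[1, 1, 1],
    numeric(1))
  expect_true(all(diff(ci4) > 0))
  # C3: better vascularized -> more radiosensitive
  pv_levels <- seq(0.02, 0.2, by = 0.02)
  p3 <- radiotherapy_plan(coupling = "C3_vascular", alpha3 = 5,
                          alpha_I = 0.5, alpha_LT = 0.5)
  ci3 <- vapply(pv_levels, function(v)
    compute_coupling(p3, f$phiT, array(v, f$d), f$thT, 0.22)$C_I[1, 1, 1],
    numeric(1))
  expect_true(all(diff(ci3) > 0))
})

test_that("plan validation enforces parameter roles", {
  expect_error(radiotherapy_plan(dose = -1), class = "rtforecast_validation_error")
  expect_error(radiotherapy_plan(coupling = "C5_none", alpha_I = 1.2),
               class = "rtforecast_validation_error")
  expect_error(radiotherapy_plan(coupling = "C4_OER", alpha = 0.05),
               class = "rtforecast_validation_error")  # missing pretreatment mean
  expect_error(radiotherapy_plan(coupling = "C3_vascular", alpha3 = 0,
                                 alpha_I = 0.5, alpha_LT = 0.5),
               class = "rtforecast_validation_error")
})
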