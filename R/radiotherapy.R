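#' Radiotherapy plan
#'
#' A single-fraction (or multi-fraction) whole-brain irradiation event and
#' the efficacy coupling used to translate dose into immediate cell kill and
#' a long-term proliferation change. Five couplings are supported:
#'
#' * `C1_logistic` - efficacy decreases as phi_T approaches its carrying
#'   capacity: `C_I = C_LT = 1 - phi_T / theta_T`.
#' * `C2_LQ` - spatially uniform linear-quadratic response:
#'   `C_I = 1 - exp(-alpha Dose - beta Dose^2)`, `C_LT = 1 - C_I`.
#' * `C3_vascular` - efficacy increases with vascularity:
#'   `C_I = exp(-(theta_V - phi_V) alpha3)`, `C_LT = 1 - C_I`.
#' * `C4_OER` - LQ scaled by an oxygen enhancement ratio
#'   `OER = phi_V / mean(pre-treatment phi_V)`:
#'   `C_I = 1 - exp(OER (-alpha Dose - beta Dose^2))`, `C_LT = 1 - C_I`.
#' * `C5_none` - uniform full efficacy: `C_I = C_LT = 1`.
#'
#' For `C2_LQ` and `C4_OER` the efficacies `alpha_I` and `alpha_LT` are fixed
#' at 1 and the radiosensitivity `alpha` is the calibrated parameter, with
#' `beta = alpha / 14` (alpha/beta ratio of 14).
#'
#' @param dose dose in Gy (scalar, or vector for multi-fraction schedules).
#' @param t_rt delivery day(s), same length as `dose`.
#' @param coupling one of `"C1_logistic"`, `"C2_LQ"`, `"C3_vascular"`,
#'   `"C4_OER"`, `"C5_none"`.
#' @param alpha_I immediate-effect efficacy in \[0, 1\].
#' @param alpha_LT long-term efficacy, >= 0 (bounded by `alpha_LT_max`).
#' @param alpha radiosensitivity (1/Gy), used by C2/C4.
#' @param beta 1/Gy^2; defaults to `alpha / 14`.
#' @param alpha3 vascular coupling scale (C3), > 0.
#' @param phiV_pretreatment_mean mean pre-treatment phi_V over the tumor ROI
#'   (required > 0 for C4).
#' @param alpha_I_V optional distinct immediate efficacy for the vascular
#'   field; defaults to `alpha_I` (the vascular immediate effect is handled
#'   identically to the tumor one).
#' @param alpha_LT_max configured upper bound for `alpha_LT`.
#' @return An object of class `radiotherapy_plan`.
#' @export
radiotherapy_plan <- function(dose = 40, t_rt = 14.5, coupling = "C3_vascular",
                              alpha_I = 0.6, alpha_LT = 0.75,
                              alpha = 0.05, beta = alpha / 14, alpha3 = 6,
                              phiV_pretreatment_mean = NA_real_,
                              alpha_I_V = NULL, alpha_LT_max = 2) {
  couplings <- c("C1_logistic", "C2_LQ", "C3_vascular", "C4_OER", "C5_none")
  coupling <- match.arg(coupling, couplings)
  if (any(dose < 0)) validation_error("dose must be >= 0")
  if (length(t_rt) != length(dose))
    validation_error("t_rt and dose must have the same length")
  if (coupling %in% c("C2_LQ", "C4_OER")) {
    alpha_I <- 1
    alpha_LT <- 1
    beta <- alpha / 14
    if (alpha < 0) validation_error("alpha must be >= 0")
  }
  if (alpha_I < 0 || alpha_I > 1)
    validation_error("alpha_I must lie in [0, 1]")
  if (alpha_LT < 0 || alpha_LT > alpha_LT_max)
    validation_error("alpha_LT must lie in [0, %g]", alpha_LT_max)
  if (coupling == "C3_vascular" && alpha3 <= 0)
    validation_error("alpha3 must be positive for the vascular coupling")
  if (coupling == "C4_OER" &&
      (!is.finite(phiV_pretreatment_mean) || phiV_pretreatment_mean <= 0))
    validation_error("C4_OER requires a positive pre-treatment mean phi_V")
  structure(list(dose = dose, t_rt = t_rt, coupling = coupling,
                 alpha_I = alpha_I, alpha_LT = alpha_LT, alpha = alpha,
                 beta = beta, alpha3 = alpha3,
                 phiV_pretreatment_mean = phiV_pretreatment_mean,
                 alpha_I_V = alpha_I_V %||% alpha_I,
                 alpha_LT_max = alpha_LT_max),
            class = "radiotherapy_plan")
}

#' Radiotherapy efficacy coupling fields
#'
#' Evaluates the immediate (`C_I`) and long-term (`C_LT`) efficacy coupling
#' fields for the plan's coupling approach from the state at the instant of
#' irradiation. `C_I` and `C_LT` are clamped to \[0, 1\]; for the C2-C4
#' couplings `C_LT = 1 - C_I`.
#'
#' @param plan a [radiotherapy_plan()].
#' @param phi_T,phi_V fields at the irradiation time.
#' @param theta_T carrying-capacity field at the irradiation time.
#' @param theta_V scalar maximum blood volume.
#' @param dose dose for this event (defaults to the plan's first dose).
#' @return list with fields `C_I`, `C_LT` and, for C4, `OER`.
#' @export
compute_coupling <- function(plan, phi_T, phi_V, theta_T, theta_V,
                             dose = plan$dose[1]) {
  clamp01 <- function(x) {
    y <- pmin(1, pmax(0, x))
    if (!is.null(dim(x))) dim(y) <- dim(x)
    y
  }
  OER <- NULL
  switch(plan$coupling,
    C1_logistic = {
      C_I <- clamp01(1 - phi_T / pmax(theta_T, .Machine$double.xmin))
      C_LT <- C_I
    },
    C2_LQ = {
      ci <- 1 - exp(-plan$alpha * dose - plan$beta * dose^2)
      C_I <- array(ci, dim(phi_T))
      C_LT <- 1 - C_I
    },
    C3_vascular = {
      C_I <- clamp01(exp(-(theta_V - phi_V) * plan$alpha3))
      C_LT <- 1 - C_I
    },
    C4_OER = {
      if (!is.finite(plan$phiV_pretreatment_mean) ||
          plan$phiV_pretreatment_mean <= 0)
        validation_error("C4_OER requires a positive pre-treatment mean phi_V")
      OER <- phi_V / plan$phiV_pretreatment_mean
      C_I <- clamp01(1 - exp(OER * (-plan$alpha * dose - plan$beta * dose^2)))
      C_LT <- 1 - C_I
    },
    C5_none = {
      C_I <- array(1, dim(phi_T))
      C_LT <- array(1, dim(phi_T))
    })
  out <- list(C_I = C_I, C_LT = C_LT)
  if (!is.null(OER)) out$OER <- OER
  out
}

#' Immediate radiotherapy effect
#'
#' Direct reduction of a volume fraction at the time of irradiation:
#' `phi_post = phi_pre - alpha_I C_I phi_pre`. Applied to phi_T and, with the
#' same structure, to phi_V. Never increases any voxel and preserves zeros.
#'
#' @param phi_pre field before irradiation.
#' @param alpha_I immediate efficacy scalar.
#' @param C_I coupling field from [compute_coupling()].
#' @return the post-irradiation field (>= 0).
#' @export
apply_immediate_effect <- function(phi_pre, alpha_I, C_I) {
  kill <- alpha_I * C_I
  if (any(kill < -1e-12) || any(kill > 1 + 1e-12))
    validation_error("alpha_I * C_I must lie in [0, 1] everywhere")
  phi_pre - pmin(1, pmax(0, kill)) * phi_pre
}

#' Long-term radiotherapy factor
#'
#' Piecewise multiplier on the net proliferation terms:
#' `R_LT = alpha_LT * C_LT` for `t >= t_rt` and 1 before irradiation.
#'
#' @param t current time (day).
#' @param plan a [radiotherapy_plan()].
#' @param C_LT long-term coupling field (evaluated at the irradiation time
#'   and frozen thereafter, unless the simulation is configured to recompute
#'   it).
#' @return scalar 1, or the field `alpha_LT * C_LT`.
#' @export
long_term_factor <- function(t, plan, C_LT) {
  if (t < min(plan$t_rt)) return(1)
  plan$alpha_LT * C_LT
}
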