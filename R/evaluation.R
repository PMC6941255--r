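#' Forecast beyond the calibration window
#'
#' Re-runs the full trajectory from the subject's first time point with the
#' calibrated (frozen) parameters and returns the state at the requested
#' forecast times (typically the two measured time points held out of
#' calibration).
#'
#' @param calibration a [calibrate()] result (or a named list of natural-
#'   scale parameter values for the problem's free parameters).
#' @param problem the [calibration_problem()] that produced it.
#' @param forecast_times days to forecast at.
#' @return A [field_series()] at `forecast_times`.
#' @export
forecast <- function(calibration, problem, forecast_times) {
  est <- if (inherits(calibration, "calibration_result"))
    calibration$estimate else calibration
  theta <- problem$theta0
  for (nm in names(est)) {
    if (nm %in% names(theta))
      theta[[nm]] <- par_transform(est[[nm]], problem$pspec[[nm]])
  }
  mdl <- problem_model(problem, theta)
  cfg <- problem$sim_config
  cfg$output_times <- forecast_times
  initial <- list(phi_T = problem$series$phi_T[[1]],
                  phi_V = problem$series$phi_V[[1]],
                  time = problem$series$times[1])
  simulate_growth(initial, mdl$params, mdl$plan, problem$mech, problem$grid,
                  cfg)
}

#' Tumor volume from a thresholded field
#'
#' Number of voxels with `phi_T >= threshold` times the physical voxel
#' volume.
#'
#' @param phi_T field.
#' @param threshold tumor-definition level in (0, 1).
#' @param grid the grid.
#' @return volume in mm^3.
#' @export
tumor_volume <- function(phi_T, threshold, grid) {
  if (threshold <= 0 || threshold >= 1)
    validation_error("threshold must lie in (0, 1)")
  sum(phi_T >= threshold) * prod(grid$spacing)
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 indicates perfect overlap. Two empty
#' masks are defined to agree perfectly (Dice 1).
#'
#' @param mask_pred,mask_meas logical arrays on the same grid.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(mask_pred, mask_meas) {
  a <- sum(mask_pred)
  b <- sum(mask_meas)
  if (a + b == 0) return(1)
  2 * sum(mask_pred & mask_meas) / (a + b)
}

#' Lin's concordance correlation coefficient
#'
#' `2 cov(p, m) / (var(p) + var(m) + (mean(p) - mean(m))^2)` with population
#' (1/n) moments: voxelwise agreement penalizing both correlation loss and
#' location/scale shifts. Degenerate cases: both inputs constant returns 1
#' when the constants agree and 0 otherwise.
#'
#' @param pred,meas paired numeric vectors (length >= 2).
#' @return scalar in \[-1, 1\].
#' @export
ccc <- function(pred, meas) {
  if (length(pred) != length(meas) || length(pred) < 2)
    validation_error("need >= 2 paired values")
  n <- length(pred)
  mp <- mean(pred); mm <- mean(meas)
  vp <- mean((pred - mp)^2); vm <- mean((meas - mm)^2)
  cv <- mean((pred - mp) * (meas - mm))
  den <- vp + vm + (mp - mm)^2
  if (den == 0) return(1)
  2 * cv / den
}

#' Score a forecast against measurements
#'
#' Per forecast time: the signed percent error in thresholded tumor volume
#' `100 (V_pred - V_meas) / V_meas`, the Dice coefficient of the thresholded
#' masks, and the concordance correlation of phi_T and phi_V over the union
#' of the predicted and measured tumor masks.
#'
#' @param forecast_series predicted [field_series()].
#' @param measured_series measured [field_series()] (matched by time; every
#'   forecast time must be measured).
#' @param threshold tumor-definition level for volume and Dice.
#' @param grid the grid.
#' @return An object of class `prediction_report`: a data frame with columns
#'   `time`, `volume_pred_mm3`, `volume_meas_mm3`, `volume_percent_error`,
#'   `dice`, `ccc_phiT`, `ccc_phiV`, plus the threshold as an attribute.
#' @export
evaluate_prediction <- function(forecast_series, measured_series, threshold,
                                grid) {
  rows <- lapply(seq_along(forecast_series$times), function(i) {
    t <- forecast_series$times[i]
    mi <- which(abs(measured_series$times - t) < 1e-9)
    if (length(mi) != 1)
      validation_error("no measurement at forecast time %g", t)
    pT <- forecast_series$phi_T[[i]]
    pV <- forecast_series$phi_V[[i]]
    mT <- measured_series$phi_T[[mi]]
    mV <- measured_series$phi_V[[mi]]
    mask_p <- grid$brain_mask & (pT >= threshold)
    mask_m <- grid$brain_mask & (mT >= threshold)
    vp <- tumor_volume(pT, threshold, grid)
    vm <- tumor_volume(mT, threshold, grid)
    supp <- mask_p | mask_m
    data.frame(time = t,
               volume_pred_mm3 = vp, volume_meas_mm3 = vm,
               volume_percent_error = if (vm > 0) 100 * (vp - vm) / vm else NA_real_,
               dice = dice(mask_p, mask_m),
               ccc_phiT = if (sum(supp) >= 2) ccc(pT[supp], mT[supp]) else NA_real_,
               ccc_phiV = if (sum(supp) >= 2) ccc(pV[supp], mV[supp]) else NA_real_,
               n_voxels = sum(supp))
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  class(out) <- c("prediction_report", class(out))
  out
}

#' Fused agreement map
#'
#' Codes each voxel 0 (background or agreement outside tumor), 1 (predicted
#' and measured tumor agree), 2 (model-only tumor), 3 (measurement-only
#' tumor), mirroring fused white/green/pink difference images.
#'
#' @param mask_pred,mask_meas logical tumor masks.
#' @return integer 3D array.
#' @export
fused_difference_map <- function(mask_pred, mask_meas) {
  out <- array(0L, dim(mask_pred))
  out[mask_pred & mask_meas] <- 1L
  out[mask_pred & !mask_meas] <- 2L
  out[!mask_pred & mask_meas] <- 3L
  out
}
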