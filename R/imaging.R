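#' Imaging derivation parameters
#'
#' Constants for converting raw imaging surrogates into model inputs: the
#' ADC-to-cellularity linear map, the DCE area-under-curve window, and the
#' relative-enhancement tumor ROI definition.
#'
#' @param ADC_w free-water apparent diffusion coefficient at 37 C (mm^2/s),
#'   default 3.0e-3.
#' @param ADC_min minimum ADC observed within tumor ROIs across the cohort
#'   (mm^2/s); must satisfy `0 < ADC_min < ADC_w`.
#' @param enhancement_threshold post/pre contrast ratio defining the tumor
#'   ROI, default 1.5.
#' @param auc_window integration window from bolus arrival in seconds,
#'   default 60.
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(ADC_w = 3.0e-3, ADC_min = 0.5e-3,
                           enhancement_threshold = 1.5, auc_window = 60) {
  if (!(ADC_w > ADC_min && ADC_min > 0))
    validation_error("need ADC_w > ADC_min > 0")
  if (auc_window <= 0) validation_error("auc_window must be positive")
  if (enhancement_threshold <= 0)
    validation_error("enhancement_threshold must be positive")
  structure(list(ADC_w = ADC_w, ADC_min = ADC_min,
                 enhancement_threshold = enhancement_threshold,
                 auc_window = auc_window),
            class = "imaging_params")
}

#' Tumor cell fraction from an ADC map
#'
#' Linear cellularity estimate `phi_T = (ADC_w - ADC) / (ADC_w - ADC_min)`,
#' clipped to \[0, 1\] and zeroed outside the brain mask. Affine and
#' order-reversing in ADC: free water maps to 0, the cohort minimum to 1.
#'
#' @param adc_map ADC field (mm^2/s).
#' @param params an [imaging_params()].
#' @param brain_mask optional logical mask; voxels outside are set to 0.
#' @return phi_T field in \[0, 1\].
#' @export
adc_to_phiT <- function(adc_map, params, brain_mask = NULL) {
  den <- params$ADC_w - params$ADC_min
  if (den <= 0) validation_error("ADC_w must exceed ADC_min")
  phi <- (params$ADC_w - adc_map) / den
  phi <- pmin(1, pmax(0, phi))
  if (!is.null(brain_mask)) phi[!brain_mask] <- 0
  if (is.array(adc_map)) dim(phi) <- dim(adc_map)
  phi
}

# trapezoidal integral of y(t) over [a, b], linearly interpolating the
# endpoints when they fall between samples
trapz_window <- function(t, y, a, b) {
  if (a < t[1] - 1e-9 || b > t[length(t)] + 1e-9)
    validation_error("curves do not cover the integration window [%g, %g] s", a, b)
  inside <- t > a & t < b
  tt <- c(a, t[inside], b)
  yy <- c(stats::approx(t, y, xout = a)$y, y[inside],
          stats::approx(t, y, xout = b)$y)
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

#' Blood volume fraction from DCE time courses
#'
#' `phi_V = AUC(tissue) / AUC(AIF)` over the first `auc_window` seconds from
#' bolus arrival, by trapezoidal integration; clipped to \[0, 1\]. Bolus
#' arrival is the first sample where the arterial input function exceeds 10%
#' of its peak. Invariant to rescaling both curves by a common factor.
#'
#' @param tissue_curves matrix of contrast-agent concentration time courses,
#'   one row per voxel, columns matching `times`.
#' @param times common time base in seconds.
#' @param aif arterial input function sampled on `times`.
#' @param params an [imaging_params()].
#' @return numeric vector of phi_V estimates, one per row.
#' @export
dce_to_phiV <- function(tissue_curves, times, aif, params) {
  if (is.null(dim(tissue_curves)))
    tissue_curves <- matrix(tissue_curves, nrow = 1)
  if (ncol(tissue_curves) != length(times) || length(aif) != length(times))
    validation_error("curves and AIF must share the time base")
  peak <- max(aif)
  if (peak <= 0) validation_error("AIF is identically nonpositive")
  t0 <- times[which(aif > 0.1 * peak)[1]]
  t1 <- t0 + params$auc_window
  if (t1 > times[length(times)] + 1e-9)
    validation_error("curves shorter than the %g s window from bolus arrival",
                     params$auc_window)
  auc_aif <- trapz_window(times, aif, t0, t1)
  if (auc_aif <= 0) validation_error("AIF area under the curve is zero")
  auc_tis <- apply(tissue_curves, 1, function(y) trapz_window(times, y, t0, t1))
  pmin(1, pmax(0, auc_tis / auc_aif))
}

#' Tumor ROI from relative enhancement
#'
#' Thresholds the post/pre contrast ratio inside the brain and keeps the
#' largest 6-connected component. Voxels with nonpositive pre-contrast
#' intensity are masked out with a warning.
#'
#' @param post_contrast,pre_contrast intensity fields.
#' @param params an [imaging_params()] (supplies the threshold).
#' @param grid the grid (supplies the brain mask).
#' @return logical tumor mask.
#' @export
segment_tumor_roi <- function(post_contrast, pre_contrast, params, grid) {
  bm <- grid$brain_mask
  bad <- bm & (pre_contrast <= 0)
  if (any(bad)) {
    warning(sprintf("%d brain voxel(s) with nonpositive pre-contrast intensity masked out",
                    sum(bad)))
    bm <- bm & !bad
  }
  ratio <- array(0, grid$dims)
  ratio[bm] <- post_contrast[bm] / pre_contrast[bm]
  mask <- bm & (ratio >= params$enhancement_threshold)
  if (!any(mask)) return(mask)
  largest_component(mask)
}

#' Voxelwise mono-exponential ADC fit
#'
#' Log-linear least-squares fit of `S(b) = S0 exp(-b ADC)` per voxel from
#' diffusion-weighted signals at the given b-values.
#'
#' @param signals matrix, one row per voxel, one column per b-value; all
#'   entries must be positive.
#' @param bvalues b-values in s/mm^2 (default 150, 500, 1100).
#' @return numeric vector of ADC estimates (mm^2/s).
#' @export
fit_adc <- function(signals, bvalues = c(150, 500, 1100)) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  if (ncol(signals) != length(bvalues))
    validation_error("signals must have one column per b-value")
  if (any(signals <= 0))
    validation_error("signals must be positive for the log-linear fit")
  b <- bvalues - mean(bvalues)
  ly <- log(signals)
  ly_c <- ly - rowMeans(ly)
  -as.numeric(ly_c %*% b) / sum(b^2)
}
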