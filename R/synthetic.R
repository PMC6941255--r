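#' Phantom subject specification
#'
#' Describes a fully synthetic subject with the temporal structure of the
#' study design: an ellipsoidal brain, a smooth tumor seed evolved under a
#' known generating model, a single-fraction whole-brain irradiation at day
#' 14.5 (20 or 40 Gy), and measurements at days 10, 12, 14, 16.5, 18.5, 20.5
#' and 22.5. The desk-scale default grid is 32 x 32 x 8 voxels at
#' 1 x 1 x 2 mm (the 32 x 32 x 16 mm^3 field of view of the full-scale
#' 128 x 128 x 16 sampling matrix, coarsened 4x in-plane and 2x through
#' plane) so that calibration experiments run in minutes; pass
#' `dims = c(128, 128, 16), spacing = c(0.25, 0.25, 1)` for the full-scale
#' matrix.
#'
#' @param dims,spacing grid dimensions and voxel spacing (mm).
#' @param brain_semi_axes ellipsoid semi-axes in mm (default 45% of the FOV).
#' @param seed_center tumor seed centre in mm (default: offset from the brain
#'   centre); must lie inside the brain.
#' @param seed_radius tumor seed radius in mm (> 0).
#' @param seed_amplitude peak initial phi_T of the seed.
#' @param phiV_interior,phiV_surface blood volume fraction deep in the brain
#'   and at the brain surface; the initial phi_V decays from the surface
#'   value with depth (length scale `phiV_length` mm), emulating the high
#'   vascularity observed near the brain-skull interface.
#' @param phiV_length decay length (mm) of the periphery-high phi_V profile.
#' @param params generating [growth_parameters()] (truth).
#' @param plan generating [radiotherapy_plan()] (truth); coupling and
#'   locality select the generating model.
#' @param kpv_local logical: generate with a locally varying k_pV field drawn
#'   around the global value (range +/- `kpv_local_spread` relative).
#' @param kpv_local_spread relative spread of local k_pV draws.
#' @param times measurement days.
#' @param noise_sd additive Gaussian measurement noise on both fraction maps
#'   (truncated to \[0, 1\]).
#' @param phiT_roi_only logical: noisy phi_T maps are supported on the tumor
#'   ROI only (the ADC map they emulate is estimated within the ROI), the
#'   realistic default. `FALSE` gives whole-brain additive noise on phi_T,
#'   the idealized measurement model used by the parameter-recovery
#'   experiments.
#' @param tumor_threshold phi_T level defining tumor masks.
#' @param sim_config [simulation_config()] used to evolve the truth.
#' @param rng_seed integer seed; all randomness flows through it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(32, 32, 8), spacing = c(1, 1, 2),
                         brain_semi_axes = NULL,
                         seed_center = NULL, seed_radius = 2.5,
                         seed_amplitude = 0.4,
                         phiV_interior = 0.03, phiV_surface = 0.20,
                         phiV_length = 3,
                         params = growth_parameters(),
                         plan = radiotherapy_plan(),
                         kpv_local = FALSE, kpv_local_spread = 0.3,
                         times = c(10, 12, 14, 16.5, 18.5, 20.5, 22.5),
                         noise_sd = 0.02, phiT_roi_only = TRUE,
                         tumor_threshold = NULL,
                         sim_config = NULL, rng_seed = 1L) {
  if (seed_radius <= 0) validation_error("seed_radius must be positive")
  if (noise_sd < 0) validation_error("noise_sd must be >= 0")
  if (is.unsorted(times, strictly = TRUE))
    validation_error("times must be strictly increasing")
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 brain_semi_axes = brain_semi_axes,
                 seed_center = seed_center, seed_radius = seed_radius,
                 seed_amplitude = seed_amplitude,
                 phiV_interior = phiV_interior, phiV_surface = phiV_surface,
                 phiV_length = phiV_length,
                 params = params, plan = plan,
                 kpv_local = isTRUE(kpv_local),
                 kpv_local_spread = kpv_local_spread,
                 times = as.numeric(times), noise_sd = noise_sd,
                 phiT_roi_only = isTRUE(phiT_roi_only),
                 tumor_threshold = tumor_threshold %||% params$theta_min,
                 sim_config = sim_config, rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Build a phantom subject
#'
#' Deterministic given the spec's seed. The tumor seed is a smooth radial
#' bump of phi_T inside the brain; phi_V starts high near the brain surface
#' and decays with depth. For locally parameterized generating models the
#' true k_pV field is drawn uniformly around the global value on the
#' calibration site layout of the seed tumor.
#'
#' @param spec a [phantom_spec()].
#' @return list with `grid`, `mech`, `initial` (a one-time-point
#'   [field_series()]), and `truth` (generating parameters, plan and spec).
#' @export
make_phantom <- function(spec) {
  grid <- make_grid(spec$dims, spec$spacing,
                    ellipsoid_mask(spec$dims, spec$spacing,
                                   spec$brain_semi_axes))
  bm <- grid$brain_mask
  ctr <- (spec$dims - 1) / 2 * spec$spacing
  seed_center <- spec$seed_center %||% (ctr + c(0.1, 0.075, 0) * spec$dims * spec$spacing / 2)
  xyz <- voxel_coords(grid)
  r2 <- (xyz[, 1] - seed_center[1])^2 + (xyz[, 2] - seed_center[2])^2 +
    (xyz[, 3] - seed_center[3])^2
  ctr_idx <- which.min(r2)
  if (!bm[ctr_idx])
    validation_error("tumor seed centre lies outside the brain")
  phiT <- array(spec$seed_amplitude * exp(-r2 / (spec$seed_radius^2 / 2)),
                spec$dims)
  phiT[phiT < 1e-4] <- 0
  phiT[!bm] <- 0

  depth <- array(cpp_edt(as.logical(bm), grid$dims, grid$spacing), grid$dims)
  phiV <- array(spec$phiV_interior +
                  (spec$phiV_surface - spec$phiV_interior) *
                  exp(-pmax(depth - min(depth[bm]), 0) / spec$phiV_length),
                spec$dims)
  phiV[!bm] <- 0

  params <- spec$params
  set.seed(spec$rng_seed)
  if (spec$kpv_local) {
    tum0 <- bm & (phiT >= spec$tumor_threshold)
    lay <- local_site_layout(tum0, grid)
    kv <- params$k_pV
    coarse <- stats::runif(length(lay$sites),
                           kv * (1 - spec$kpv_local_spread),
                           kv * (1 + spec$kpv_local_spread))
    params$k_pV <- expand_local_field(coarse, tum0, grid, background = kv)
    truth_kpv_coarse <- coarse
  } else {
    truth_kpv_coarse <- NULL
  }
  mech <- mechanical_state(grid, lambda1 = params$lambda1)
  initial <- field_series(times = spec$times[1], phi_T = list(phiT),
                          phi_V = list(phiV),
                          tumor_masks = list(bm & (phiT >= spec$tumor_threshold)))
  list(grid = grid, mech = mech, initial = initial,
       truth = list(params = params, plan = spec$plan,
                    kpv_coarse = truth_kpv_coarse, spec = spec))
}

#' Generate noiseless truth and noisy measurements for a phantom
#'
#' Evolves the phantom under its generating model to every scheduled
#' measurement day, then adds voxelwise Gaussian noise (sd `spec$noise_sd`)
#' truncated to \[0, 1\] inside the brain. Tumor masks come from the truth
#' phi_T thresholded at the spec's tumor threshold. Reproducible given the
#' spec seed; different seeds share the truth and differ only in noise.
#'
#' @param phantom output of [make_phantom()].
#' @param spec the [phantom_spec()].
#' @param noise_seed optional separate seed for the noise draw (defaults to
#'   `spec$rng_seed + 1`).
#' @param truth optional precomputed truth [field_series()] for this phantom
#'   (e.g. from a previous call), to avoid re-simulating when drawing several
#'   noise realizations of the same subject.
#' @return list with `truth` and `noisy` [field_series()].
#' @export
generate_measurements <- function(phantom, spec, noise_seed = NULL,
                                  truth = NULL) {
  cfg <- spec$sim_config %||% simulation_config(
    output_times = spec$times, tumor_threshold = spec$tumor_threshold)
  cfg$output_times <- spec$times
  truth <- truth %||% simulate_growth(phantom$initial, phantom$truth$params,
                                      phantom$truth$plan, phantom$mech,
                                      phantom$grid, cfg)
  bm <- phantom$grid$brain_mask
  set.seed(noise_seed %||% (spec$rng_seed + 1L))
  add_noise <- function(f, support = bm) {
    if (spec$noise_sd == 0) return(f)   # noiseless path: exact truth
    g <- f + array(stats::rnorm(length(f), 0, spec$noise_sd), dim(f))
    g <- pmin(1, pmax(0, g))
    g[!support] <- 0
    array(g, dim(f))
  }
  # noisy cellularity maps are supported on the tumor ROI (the ADC map is
  # estimated within the ROI); blood volume maps cover the whole brain
  noisy <- field_series(
    times = truth$times,
    phi_T = lapply(seq_along(truth$times), function(i)
      add_noise(truth$phi_T[[i]],
                if (spec$phiT_roi_only) truth$tumor_masks[[i]] else bm)),
    phi_V = lapply(truth$phi_V, add_noise),
    tumor_masks = truth$tumor_masks)
  list(truth = truth, noisy = noisy)
}

# gamma-variate arterial input function (concentration vs seconds)
gamma_variate_aif <- function(times, t0 = 10, shape = 3, scale = 6,
                              amplitude = 1) {
  tt <- pmax(times - t0, 0)
  amplitude * (tt / (shape * scale))^shape * exp(shape - tt / scale)
}

#' Emit raw imaging surrogates from truth fields
#'
#' Constructs ADC maps as the exact inverse of the linear cellularity map
#' (`ADC = ADC_w - phi_T (ADC_w - ADC_min)`), optional three-b-value DW
#' signals, DCE tissue time courses proportional to the arterial input
#' function (`tissue = phi_V * AIF`), and pre/post contrast volumes whose
#' ratio is 2 inside the tumor mask and 1 elsewhere. Applying the imaging
#' derivation operators to these outputs recovers the noiseless truth fields
#' exactly.
#'
#' @param truth a truth [field_series()].
#' @param imaging an [imaging_params()].
#' @param spec the [phantom_spec()] (supplies the grid geometry via dims).
#' @param grid the grid.
#' @param time_index which time point to emit (default 1).
#' @param dce_times DCE sampling grid in seconds.
#' @return list with `adc`, `dw_signals`, `dce` (tissue curve matrix over
#'   brain voxels, in `which(brain_mask)` order), `dce_times`, `aif`,
#'   `pre_contrast`, `post_contrast`, `brain_index`.
#' @export
emit_raw_surrogates <- function(truth, imaging, spec, grid, time_index = 1,
                                dce_times = seq(0, 90, by = 1.5)) {
  bm <- grid$brain_mask
  phiT <- truth$phi_T[[time_index]]
  phiV <- truth$phi_V[[time_index]]
  tum <- truth$tumor_masks[[time_index]]
  adc <- imaging$ADC_w - phiT * (imaging$ADC_w - imaging$ADC_min)
  bvals <- c(150, 500, 1100)
  idx <- which(bm)
  dw <- outer(adc[idx], bvals, function(a, b) exp(-a * b))
  aif <- gamma_variate_aif(dce_times)
  dce <- phiV[idx] %o% aif
  pre <- array(100, grid$dims)
  post <- pre * (1 + as.numeric(tum))
  list(adc = adc, dw_signals = dw, dce = dce, dce_times = dce_times,
       aif = aif, pre_contrast = pre, post_contrast = post,
       brain_index = idx)
}
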