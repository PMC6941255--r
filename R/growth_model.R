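#' Growth model parameters
#'
#' All calibratable or assigned constants of the coupled tumor / vasculature
#' reaction-diffusion model. Rates are per day, diffusivities in mm^2/day,
#' volume fractions dimensionless.
#'
#' @param D_T0,D_V0 tumor / vascular diffusion coefficients in the absence of
#'   mechanical coupling (mm^2/day), >= 0.
#' @param k_pT tumor cell proliferation rate (1/day), global scalar.
#' @param k_pV vasculature proliferation rate (1/day): a scalar for the
#'   global parameterization, or a 3D field for the locally calibrated one.
#' @param k_dV vasculature death rate (1/day).
#' @param lambda1 stress-diffusion coupling constant (1/Pa).
#' @param phiV_thresh threshold on phi_V below which the tumor carrying
#'   capacity decreases, in (0, theta_V].
#' @param theta_max,theta_min maximum / minimum tumor cell carrying capacity,
#'   0 < theta_min <= theta_max <= 1. theta_min is assigned per subject as the
#'   lowest measured in-tumor phi_T across the calibration time points.
#' @param theta_V maximum blood volume fraction (carrying capacity of phi_V),
#'   assigned per subject as the largest measured phi_V.
#' @return An object of class `growth_parameters`.
#' @export
growth_parameters <- function(D_T0 = 0.05, D_V0 = 0.02, k_pT = 0.5,
                              k_pV = 0.25, k_dV = 0.15, lambda1 = 2e-3,
                              phiV_thresh = 0.10, theta_max = 0.85,
                              theta_min = 0.05, theta_V = 0.22) {
  for (nm in c("D_T0", "D_V0", "k_pT", "k_dV", "lambda1")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) || val < 0)
      validation_error("%s must be a nonnegative scalar", nm)
  }
  if (any(k_pV < 0)) validation_error("k_pV must be nonnegative")
  if (!(theta_min > 0 && theta_min <= theta_max && theta_max <= 1))
    validation_error("need 0 < theta_min <= theta_max <= 1")
  if (!(theta_V > 0 && theta_V <= 1))
    validation_error("need 0 < theta_V <= 1")
  if (!(phiV_thresh > 0 && phiV_thresh <= theta_V))
    validation_error("need 0 < phiV_thresh <= theta_V")
  structure(list(D_T0 = D_T0, D_V0 = D_V0, k_pT = k_pT, k_pV = k_pV,
                 k_dV = k_dV, lambda1 = lambda1, phiV_thresh = phiV_thresh,
                 theta_max = theta_max, theta_min = theta_min,
                 theta_V = theta_V),
            class = "growth_parameters")
}

#' Vascularity-dependent tumor carrying capacity
#'
#' Piecewise-linear map from blood volume fraction to the tumor cell carrying
#' capacity: `theta_max` wherever `phi_V >= phiV_thresh`, and
#' `theta_min + phi_V (theta_max - theta_min) / phiV_thresh` below the
#' threshold. Continuous and nondecreasing in `phi_V`.
#'
#' @param phi_V blood volume fraction field (or vector).
#' @param params a [growth_parameters()].
#' @return theta_T with the same shape as `phi_V`.
#' @export
carrying_capacity <- function(phi_V, params) {
  if (params$phiV_thresh <= 0)
    validation_error("phiV_thresh must be positive")
  lin <- params$theta_min +
    phi_V * (params$theta_max - params$theta_min) / params$phiV_thresh
  out <- ifelse(phi_V >= params$phiV_thresh, params$theta_max, lin)
  if (is.array(phi_V)) dim(out) <- dim(phi_V)
  out
}

#' Normalized distance to the tumor periphery
#'
#' Physical (spacing-aware) Euclidean distance from every tumor voxel to the
#' nearest non-tumor voxel, linearly rescaled so the shallowest (peripheral)
#' voxels map to d = 1 and the deepest voxel maps to d = 0. Zero outside the
#' tumor. When all tumor voxels are equally deep (single voxel or thin
#' shell), d = 1 everywhere in the tumor: periphery semantics dominate.
#'
#' @param tumor_mask logical 3D array, nonempty.
#' @param grid the grid.
#' @return d field in \[0, 1\].
#' @export
distance_to_periphery <- function(tumor_mask, grid) {
  if (!any(tumor_mask)) validation_error("tumor mask is empty")
  if (!identical(dim(tumor_mask), grid$dims))
    validation_error("tumor mask dims do not match grid")
  if (all(tumor_mask)) return(array(1, grid$dims))  # no periphery: degenerate
  dist <- array(cpp_edt(as.logical(tumor_mask), grid$dims, grid$spacing),
                grid$dims)
  dmin <- min(dist[tumor_mask])
  dmax <- max(dist[tumor_mask])
  d <- array(0, grid$dims)
  if (dmax > dmin) {
    d[tumor_mask] <- (dmax - dist[tumor_mask]) / (dmax - dmin)
  } else {
    d[tumor_mask] <- 1
  }
  d
}

#' Derived model fields
#'
#' Convenience bundle of the carrying-capacity fields and the
#' distance-to-periphery field for a given state.
#'
#' @param phi_V blood volume fraction field.
#' @param tumor_mask logical tumor mask (may be empty: d is then all zero and
#'   the vascular reactions are inactive).
#' @param params growth parameters.
#' @param grid the grid.
#' @return list with `theta_T`, `theta_TV`, `d`, `tumor_mask`.
#' @export
derived_fields <- function(phi_V, tumor_mask, params, grid) {
  theta_T <- carrying_capacity(phi_V, params)
  d <- if (any(tumor_mask)) distance_to_periphery(tumor_mask, grid)
       else array(0, grid$dims)
  list(theta_T = theta_T, theta_TV = theta_T + params$theta_V, d = d,
       tumor_mask = tumor_mask)
}

# Flux-conservative variable-coefficient diffusion term with harmonic-mean
# face diffusivities and no-flux closure at the brain-mask surface.
diffusion_term <- function(phi, D, grid) {
  bm <- grid$brain_mask
  h <- grid$spacing
  out <- array(0, grid$dims)
  for (ax in 1:3) {
    php <- shift3(phi, ax, -1)
    phm <- shift3(phi, ax, +1)
    Dp <- shift3(D, ax, -1)
    Dm <- shift3(D, ax, +1)
    inp <- shift3(bm, ax, -1, FALSE) & bm
    inm <- shift3(bm, ax, +1, FALSE) & bm
    sp <- D + Dp
    sm <- D + Dm
    Gp <- ifelse(inp & sp > 0, 2 * D * Dp / pmax(sp, .Machine$double.xmin), 0)
    Gm <- ifelse(inm & sm > 0, 2 * D * Dm / pmax(sm, .Machine$double.xmin), 0)
    out <- out + (Gp * (php - phi) - Gm * (phi - phm)) / h[ax]^2
  }
  out[!bm] <- 0
  out
}

#' Tumor cell fraction right-hand side
#'
#' `d phi_T / dt = div(D_T grad phi_T) + R_LT k_pT phi_T (1 - (phi_T + phi_V)
#' / theta_TV)`: mechanically damped diffusion plus logistic growth against
#' the combined tumor + vascular carrying capacity, with the long-term
#' radiotherapy factor scaling the proliferation term. This is the reference
#' (pure R) evaluation; the simulator's compiled stepper implements the same
#' discretization and is cross-checked against it.
#'
#' @param phi_T,phi_V current fields.
#' @param D_T_field damped tumor diffusivity field from [damp_diffusion()].
#' @param params growth parameters.
#' @param derived a [derived_fields()] bundle.
#' @param R_LT long-term radiotherapy factor (scalar or field; 1 before
#'   irradiation).
#' @param grid the grid.
#' @return rate field (1/day), zero outside the brain mask.
#' @export
tumor_rhs <- function(phi_T, phi_V, D_T_field, params, derived, R_LT, grid) {
  bm <- grid$brain_mask
  thTV <- derived$theta_TV
  bad <- bm & (thTV <= 0) & (phi_T > 0)
  if (any(bad))
    numerical_error("combined carrying capacity is zero at %d voxel(s) with positive phi_T (first linear index %d)",
                    sum(bad), which(bad)[1])
  reac <- R_LT * params$k_pT * phi_T * ifelse(thTV > 0, 1 - (phi_T + phi_V) / pmax(thTV, .Machine$double.xmin), 0)
  out <- diffusion_term(phi_T, D_T_field, grid) + reac
  out[!bm] <- 0
  out
}

#' Blood volume fraction right-hand side
#'
#' `d phi_V / dt = div(D_V grad phi_V) + R_LT_V k_pV d phi_V (1 - phi_V /
#' theta_V) - k_dV (1 - d) phi_V`: damped diffusion, angiogenesis strongest
#' at the tumor periphery (d = 1) and vascular death strongest at depth
#' (d = 0). The two reaction terms act only inside the tumor mask, where the
#' distance field is defined; outside the tumor the vasculature evolves by
#' diffusion alone.
#'
#' @param phi_V,phi_T current fields.
#' @param D_V_field damped vascular diffusivity field.
#' @param params growth parameters (`k_pV` scalar or field).
#' @param derived a [derived_fields()] bundle (supplies `d` and the tumor
#'   mask).
#' @param R_LT_V long-term radiotherapy factor on the vascular growth term.
#' @param grid the grid.
#' @return rate field (1/day), zero outside the brain mask.
#' @export
vascular_rhs <- function(phi_V, phi_T, D_V_field, params, derived, R_LT_V,
                         grid) {
  bm <- grid$brain_mask
  kpV <- params$k_pV
  if (length(kpV) == 1) kpV <- array(kpV, grid$dims)
  d <- derived$d
  tum <- derived$tumor_mask
  reac <- ifelse(tum,
                 R_LT_V * kpV * d * phi_V * (1 - phi_V / params$theta_V) -
                   params$k_dV * (1 - d) * phi_V,
                 0)
  out <- diffusion_term(phi_V, D_V_field, grid) + reac
  out[!bm] <- 0
  out
}
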