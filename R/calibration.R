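#' Model identifiers
#'
#' The model family crosses five radiotherapy couplings with two k_pV
#' parameterizations, giving the ten calibratable models.
#'
#' @return character vector of the ten model ids, e.g. `"C3_global"`.
#' @export
model_ids <- function() {
  as.vector(outer(c("C1", "C2", "C3", "C4", "C5"), c("global", "local"),
                  paste, sep = "_"))
}

coupling_of <- function(model_id) {
  code <- sub("_.*$", "", model_id)
  c(C1 = "C1_logistic", C2 = "C2_LQ", C3 = "C3_vascular", C4 = "C4_OER",
    C5 = "C5_none")[[code]]
}

is_local <- function(model_id) grepl("_local$", model_id)

# Calibration site layout for locally varying k_pV: the in-plane bounding box
# of the tumor is tiled with 3 x 3 x 1 voxel blocks anchored at the bounding
# box corner. In blocks whose full 3 x 3 footprint lies inside the bounding
# box, the calibrated sites are the block's four corners and centre
# (intersected with the tumor mask; if none is a tumor voxel all tumor voxels
# of the block are calibrated directly); partial edge blocks calibrate all
# their tumor voxels directly. Every other tumor voxel is interpolated from
# the nearest calibrated site of its block (in-plane physical distance, ties
# broken by site order: corners column-major, then centre).
local_site_layout <- function(tumor_mask, grid) {
  if (!any(tumor_mask)) validation_error("tumor mask is empty")
  d <- grid$dims
  idx <- which(tumor_mask)
  ijk <- arrayInd(idx, d)
  i0 <- min(ijk[, 1]); i1 <- max(ijk[, 1])
  j0 <- min(ijk[, 2]); j1 <- max(ijk[, 2])
  sites <- integer(0)          # full-grid linear indices, in order
  assign_site <- integer(length(idx))  # per tumor voxel: site number
  vox_lin <- function(i, j, k) i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]
  site_no <- setNames(integer(0), character(0))
  for (bi in seq(i0, i1, by = 3L)) {
    for (bj in seq(j0, j1, by = 3L)) {
      complete <- (bi + 2L <= i1) && (bj + 2L <= j1)
      inblk <- ijk[, 1] >= bi & ijk[, 1] <= min(bi + 2L, i1) &
               ijk[, 2] >= bj & ijk[, 2] <= min(bj + 2L, j1)
      if (!any(inblk)) next
      for (k in sort(unique(ijk[inblk, 3]))) {
        sel <- which(inblk & ijk[, 3] == k)
        if (complete) {
          tmpl <- rbind(c(bi, bj), c(bi + 2L, bj), c(bi, bj + 2L),
                        c(bi + 2L, bj + 2L), c(bi + 1L, bj + 1L))
          tl <- vox_lin(tmpl[, 1], tmpl[, 2], k)
          tl <- tl[tumor_mask[tl]]
        } else {
          tl <- integer(0)
        }
        if (length(tl) == 0) tl <- idx[sel]   # calibrate directly
        new <- setdiff(tl, sites)
        sites <- c(sites, new)
        sij <- arrayInd(tl, d)
        for (s in sel) {
          dx <- (ijk[s, 1] - sij[, 1]) * grid$spacing[1]
          dy <- (ijk[s, 2] - sij[, 2]) * grid$spacing[2]
          best <- which.min(dx^2 + dy^2)   # ties: first listed site
          assign_site[s] <- match(tl[best], sites)
        }
      }
    }
  }
  list(sites = sites, voxels = idx, assignment = assign_site)
}

#' Expand coarse k_pV values to a full field
#'
#' Places the calibrated values at their sites and fills the remaining tumor
#' voxels from the nearest calibrated site of their 3 x 3 block (see the
#' layout rule in the package's calibration documentation). Outside the tumor
#' the field takes the global baseline value.
#'
#' @param coarse_values numeric vector, one per calibration site (layout
#'   order).
#' @param tumor_mask logical mask the layout was built from.
#' @param grid the grid.
#' @param background value outside the tumor (global baseline k_pV).
#' @param layout optional precomputed [local_site_layout()] result.
#' @return full 3D k_pV field.
#' @export
expand_local_field <- function(coarse_values, tumor_mask, grid,
                               background = 0, layout = NULL) {
  lay <- layout %||% local_site_layout(tumor_mask, grid)
  if (length(coarse_values) != length(lay$sites))
    validation_error("expected %d coarse values for this layout, got %d",
                     length(lay$sites), length(coarse_values))
  fld <- array(background, grid$dims)
  fld[lay$voxels] <- coarse_values[lay$assignment]
  fld
}

# parameter transforms: positive parameters in log space, bounded ones in
# scaled-logit space, so the unconstrained LM step respects the bounds
par_transform <- function(x, spec) {
  switch(spec$type,
         log = log(x),
         logit = stats::qlogis(pmin(1 - 1e-9, pmax(1e-9, (x - spec$lo) / (spec$hi - spec$lo)))))
}
par_untransform <- function(y, spec) {
  switch(spec$type,
         log = exp(y),
         logit = spec$lo + (spec$hi - spec$lo) * stats::plogis(y))
}

#' Define a subject-specific calibration problem
#'
#' Fixes the assigned quantities from the measurements (theta_min as the
#' lowest in-tumor phi_T over the calibration time points; theta_V as the
#' largest measured phi_V; the pre-treatment mean phi_V for the
#' oxygen-enhanced coupling), chooses the free-parameter list for the model
#' id, and builds the residual evaluation mask (union of measured tumor masks
#' over the calibration window, dilated by two voxels inside the brain).
#' Calibration uses measurements at time points 2-5 with time point 1 as the
#' initial condition.
#'
#' @param series measured [field_series()] with at least 5 time points.
#' @param grid,mech domain and mechanical state.
#' @param model_id one of [model_ids()].
#' @param base_params [growth_parameters()] holding assigned values and
#'   defaults for the free parameters (initial guesses unless overridden in
#'   [calibrate()]).
#' @param dose,t_rt radiotherapy dose (Gy) and day.
#' @param free optional character vector restricting which parameters are
#'   calibrated (defaults to the model's full role list: the growth and
#'   coupling parameters of the standard parameter table).
#' @param init optional named list of initial guesses overriding
#'   `base_params` / plan defaults.
#' @param plan_args named list of fixed [radiotherapy_plan()] arguments for
#'   coupling parameters that are not calibrated.
#' @param assign optional named list overriding the data-derived assignments
#'   (`theta_min`, `theta_V`, `phiV_pretreatment_mean`, `tumor_threshold`).
#'   By default these are assigned from the measurements (the study-style
#'   procedure); recovery experiments on synthetic data pass the generating
#'   values so that the fit isolates optimizer behaviour from assignment
#'   noise.
#' @param sim_config a [simulation_config()] for the forward runs.
#' @param n_calibration_times how many leading time points form the
#'   calibration window (default 5: one initial + four fitted).
#' @return An object of class `calibration_problem`.
#' @export
calibration_problem <- function(series, grid, mech, model_id = "C3_global",
                                base_params = growth_parameters(),
                                dose = 40, t_rt = 14.5,
                                free = NULL, init = list(),
                                plan_args = list(), assign = list(),
                                sim_config = NULL,
                                n_calibration_times = 5) {
  if (!model_id %in% model_ids())
    validation_error("unknown model id '%s'", model_id)
  nt <- length(series$times)
  if (nt < n_calibration_times)
    validation_error("need at least %d measured time points", n_calibration_times)
  ct <- seq_len(n_calibration_times)
  bm <- grid$brain_mask

  # assigned quantities from the data
  tum_union <- Reduce(`|`, series$tumor_masks[ct])
  if (!any(tum_union))
    validation_error("no tumor voxels in the calibration window")
  in_tum_phiT <- unlist(lapply(ct, function(i) series$phi_T[[i]][series$tumor_masks[[i]]]))
  theta_min <- assign$theta_min %||% max(min(in_tum_phiT), 1e-3)
  theta_V <- assign$theta_V %||%
    min(max(unlist(lapply(ct, function(i) series$phi_V[[i]][bm]))), 1)
  pre <- which(series$times[ct] <= t_rt)
  phiV_pre <- assign$phiV_pretreatment_mean %||%
    mean(unlist(lapply(pre, function(i) series$phi_V[[i]][series$tumor_masks[[i]]])))

  params <- base_params
  params$theta_min <- theta_min
  params$theta_V <- theta_V
  params$theta_max <- min(max(params$theta_max, theta_min + 1e-3), 1)
  params$phiV_thresh <- min(params$phiV_thresh, theta_V)

  eval_mask <- dilate_mask(tum_union, 2, within = bm)

  coupling <- coupling_of(model_id)
  coupling_free <- switch(sub("_.*$", "", model_id),
                          C1 = c("alpha_I", "alpha_LT"),
                          C2 = "alpha",
                          C3 = c("alpha_I", "alpha_LT", "alpha3"),
                          C4 = "alpha",
                          C5 = c("alpha_I", "alpha_LT"))
  growth_free <- c("k_pT", "k_pV", "k_dV", "D_T0", "D_V0", "lambda1",
                   "phiV_thresh", "theta_max")
  free <- free %||% c(growth_free, coupling_free)

  layout <- NULL
  if (is_local(model_id) && "k_pV" %in% free) {
    layout <- local_site_layout(series$tumor_masks[[1]], grid)
  }

  # transform specs and default initial values
  defaults <- list(k_pT = params$k_pT,
                   k_pV = if (length(params$k_pV) == 1) params$k_pV else mean(params$k_pV),
                   k_dV = params$k_dV, D_T0 = params$D_T0, D_V0 = params$D_V0,
                   lambda1 = max(params$lambda1, 1e-6),
                   phiV_thresh = params$phiV_thresh,
                   theta_max = params$theta_max,
                   alpha_I = 0.5, alpha_LT = 0.5, alpha = 0.05, alpha3 = 2)
  defaults[names(init)] <- init
  tspec <- list(
    k_pT = list(type = "log"), k_pV = list(type = "log"),
    k_dV = list(type = "log"), D_T0 = list(type = "log"),
    D_V0 = list(type = "log"), lambda1 = list(type = "log"),
    alpha = list(type = "log"), alpha3 = list(type = "log"),
    alpha_I = list(type = "logit", lo = 0, hi = 1),
    alpha_LT = list(type = "logit", lo = 0, hi = 2),
    phiV_thresh = list(type = "logit", lo = 0, hi = theta_V),
    theta_max = list(type = "logit", lo = theta_min + 1e-6, hi = 1))

  theta0 <- numeric(0)
  pspec <- list()
  for (nm in free) {
    if (nm == "k_pV" && !is.null(layout)) {
      m <- length(layout$sites)
      v <- rep(defaults$k_pV, m)
      names(v) <- paste0("k_pV_", seq_len(m))
      theta0 <- c(theta0, log(v))
      for (s in names(v)) pspec[[s]] <- list(type = "log", role = "k_pV_local")
    } else {
      sp <- tspec[[nm]]
      if (is.null(sp)) validation_error("no transform for parameter '%s'", nm)
      sp$role <- nm
      pspec[[nm]] <- sp
      theta0 <- c(theta0, setNames(par_transform(defaults[[nm]], sp), nm))
    }
  }

  cfg <- sim_config %||% simulation_config()
  cfg$output_times <- series$times[ct[-1]]
  cfg$tumor_threshold <- assign$tumor_threshold %||% cfg$tumor_threshold %||%
    theta_min

  structure(list(series = series, grid = grid, mech = mech,
                 model_id = model_id, coupling = coupling,
                 params = params, dose = dose, t_rt = t_rt,
                 free = free, pspec = pspec, theta0 = theta0,
                 plan_args = plan_args,
                 layout = layout, eval_mask = eval_mask,
                 phiV_pretreatment_mean = phiV_pre,
                 calib_times = ct, sim_config = cfg),
            class = "calibration_problem")
}

# materialize growth parameters and a radiotherapy plan from a transformed
# parameter vector
problem_model <- function(problem, theta) {
  params <- problem$params
  plan_args <- list(dose = problem$dose, t_rt = problem$t_rt,
                    coupling = problem$coupling,
                    phiV_pretreatment_mean = problem$phiV_pretreatment_mean)
  plan_args[names(problem$plan_args)] <- problem$plan_args
  local_vals <- numeric(0)
  for (nm in names(problem$pspec)) {
    sp <- problem$pspec[[nm]]
    val <- par_untransform(theta[[nm]], sp)
    if (sp$role == "k_pV_local") {
      local_vals <- c(local_vals, val)
    } else if (sp$role %in% c("alpha_I", "alpha_LT", "alpha", "alpha3")) {
      plan_args[[sp$role]] <- val
    } else {
      params[[sp$role]] <- val
    }
  }
  if (length(local_vals)) {
    params$k_pV <- expand_local_field(
      local_vals, problem$series$tumor_masks[[1]], problem$grid,
      background = if (length(problem$params$k_pV) == 1) problem$params$k_pV
                   else mean(problem$params$k_pV),
      layout = problem$layout)
  }
  # keep theta_max above the assigned theta_min
  params$theta_max <- max(params$theta_max, params$theta_min + 1e-6)
  params$phiV_thresh <- min(params$phiV_thresh, params$theta_V)
  plan <- do.call(radiotherapy_plan, plan_args)
  list(params = params, plan = plan)
}

problem_residuals <- function(problem, theta) {
  mdl <- problem_model(problem, theta)
  initial <- list(phi_T = problem$series$phi_T[[1]],
                  phi_V = problem$series$phi_V[[1]],
                  time = problem$series$times[1])
  sim <- simulate_growth(initial, mdl$params, mdl$plan, problem$mech,
                         problem$grid, problem$sim_config)
  msk <- problem$eval_mask
  fit_idx <- problem$calib_times[-1]
  r <- numeric(0)
  for (i in seq_along(fit_idx)) {
    mi <- fit_idx[i]
    r <- c(r,
           sim$phi_T[[i]][msk] - problem$series$phi_T[[mi]][msk],
           sim$phi_V[[i]][msk] - problem$series$phi_V[[mi]][msk])
  }
  r
}

#' Calibration objective (sum of squared errors)
#'
#' SSE between simulated and measured phi_T and phi_V over the evaluation
#' mask at the fitted time points, equally weighted. A simulator failure
#' (instability, non-finite fields) yields a large finite penalty with
#' attribute `failed = TRUE` so the optimizer can retreat.
#'
#' @param par named list (or vector) of natural-scale values for (a subset
#'   of) the problem's free parameters; unspecified ones keep their initial
#'   values.
#' @param problem a [calibration_problem()].
#' @return scalar SSE.
#' @export
objective <- function(par, problem) {
  theta <- problem$theta0
  for (nm in names(par)) {
    if (!nm %in% names(theta))
      validation_error("'%s' is not a free parameter of this problem", nm)
    theta[[nm]] <- par_transform(par[[nm]], problem$pspec[[nm]])
  }
  r <- tryCatch(problem_residuals(problem, theta), error = function(e) e)
  if (inherits(r, "error"))
    return(structure(1e12, failed = TRUE, message = conditionMessage(r)))
  sum(r^2)
}

#' Optimizer control settings
#'
#' Knobs of the hybrid simulated-annealing Levenberg-Marquardt scheme. The
#' stopping rules are a relative SSE stagnation of less than 0.5% between
#' successive accepted iterations, or 1000 iterations. The annealing
#' temperature starts at `sa_temp_frac` times the initial SSE and cools
#' geometrically by `sa_cool` per iteration; uphill proposals are accepted
#' with Metropolis probability `exp(-dSSE / T)`.
#'
#' @param max_iter iteration cap.
#' @param rel_tol relative SSE stagnation tolerance.
#' @param fd_step central-difference step on the transformed scale (0.01
#'   is about a 1% relative step for log-scale parameters).
#' @param lm_lambda0,lm_up,lm_down initial LM damping and its up/down
#'   factors.
#' @param max_lambda_tries damping increases attempted per iteration before
#'   the proposal is rejected outright.
#' @param sa_temp_frac,sa_cool annealing schedule.
#' @param penalty SSE assigned to failed forward runs.
#' @return list of class `calibration_control`.
#' @export
calibration_control <- function(max_iter = 1000, rel_tol = 0.005,
                                fd_step = 0.01, lm_lambda0 = 1e-3,
                                lm_up = 10, lm_down = 0.3,
                                max_lambda_tries = 4,
                                sa_temp_frac = 0.1, sa_cool = 0.9,
                                penalty = 1e12) {
  structure(list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 fd_step = fd_step, lm_lambda0 = lm_lambda0, lm_up = lm_up,
                 lm_down = lm_down, max_lambda_tries = as.integer(max_lambda_tries),
                 sa_temp_frac = sa_temp_frac, sa_cool = sa_cool,
                 penalty = penalty),
            class = "calibration_control")
}

#' Calibrate a model to a subject
#'
#' Hybrid simulated-annealing Levenberg-Marquardt estimation of the problem's
#' free parameters: LM steps from a central-difference Jacobian of the
#' residual vector, with downhill proposals always accepted and uphill ones
#' accepted with Metropolis probability under a geometrically cooling
#' temperature. Terminates on SSE stagnation (< 0.5% relative change between
#' successive accepted iterations) or at the iteration cap. Reproducible
#' given `rng_seed`.
#'
#' @param problem a [calibration_problem()].
#' @param control a [calibration_control()].
#' @param rng_seed integer seed for the annealing draws.
#' @param init optional named list of natural-scale starting values
#'   overriding the problem's initial guesses.
#' @return An object of class `calibration_result`: estimated parameters
#'   (natural scale; coarse k_pV values individually for local models), the
#'   final `RSS`, the calibrated parameter count `k`, residual count `n`,
#'   iteration count, convergence flag and the objective trajectory.
#' @export
calibrate <- function(problem, control = calibration_control(),
                      rng_seed = 1L, init = NULL) {
  set.seed(rng_seed)
  theta <- problem$theta0
  if (!is.null(init)) {
    for (nm in names(init)) {
      if (!nm %in% names(theta))
        validation_error("'%s' is not a free parameter of this problem", nm)
      theta[[nm]] <- par_transform(init[[nm]], problem$pspec[[nm]])
    }
  }
  k <- length(theta)
  safe_resid <- function(th) {
    r <- tryCatch(problem_residuals(problem, th), error = function(e) NULL)
    r
  }
  r <- safe_resid(theta)
  if (is.null(r))
    numerical_error("forward run failed at the initial guess")
  n <- length(r)
  sse <- sum(r^2)
  best_theta <- theta
  best_sse <- sse
  traj <- sse
  temp <- control$sa_temp_frac * sse
  lambda <- control$lm_lambda0
  converged <- FALSE
  iter <- 0L
  sse_acc_prev <- sse

  while (iter < control$max_iter) {
    iter <- iter + 1L
    # central-difference Jacobian on the transformed scale
    J <- matrix(0, n, k)
    ok_j <- TRUE
    for (j in seq_len(k)) {
      h <- control$fd_step
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      rp <- safe_resid(tp); rm <- safe_resid(tm)
      if (is.null(rp) || is.null(rm)) { ok_j <- FALSE; break }
      J[, j] <- (rp - rm) / (2 * h)
    }
    if (!ok_j) break
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    dJ <- diag(JtJ)
    dJ[dJ < 1e-12] <- 1e-12
    accepted <- FALSE
    for (try in seq_len(control$max_lambda_tries)) {
      H <- JtJ + lambda * diag(dJ, k)
      delta <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * control$lm_up; next }
      theta_new <- theta + as.numeric(delta)
      names(theta_new) <- names(theta)
      r_new <- safe_resid(theta_new)
      sse_new <- if (is.null(r_new)) control$penalty else sum(r_new^2)
      if (sse_new < sse) {
        accepted <- TRUE
        lambda <- max(lambda * control$lm_down, 1e-12)
      } else if (is.finite(sse_new) &&
                 stats::runif(1) < exp(-(sse_new - sse) / max(temp, 1e-300))) {
        accepted <- TRUE  # simulated-annealing uphill acceptance
      } else {
        lambda <- lambda * control$lm_up
      }
      if (accepted) {
        theta <- theta_new
        r <- if (is.null(r_new)) r else r_new
        sse <- sse_new
        break
      }
    }
    traj <- c(traj, sse)
    if (sse < best_sse) {
      best_sse <- sse
      best_theta <- theta
    }
    temp <- temp * control$sa_cool
    if (accepted) {
      if (abs(sse_acc_prev - sse) <= control$rel_tol * max(sse_acc_prev, 1e-12)) {
        converged <- TRUE
        break
      }
      sse_acc_prev <- sse
    }
  }

  est <- lapply(seq_along(best_theta), function(j)
    par_untransform(best_theta[[j]], problem$pspec[[names(best_theta)[j]]]))
  names(est) <- names(best_theta)
  structure(list(model_id = problem$model_id, estimate = est,
                 theta = best_theta, RSS = best_sse, k = k, n = n,
                 iterations = iter, converged = converged,
                 trajectory = traj, rng_seed = rng_seed),
            class = "calibration_result")
}

#' @export
#' @method print calibration_result
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s: RSS = %.6g (k = %d, n = %d, %d iterations%s)\n",
              x$model_id, x$RSS, x$k, x$n, x$iterations,
              if (x$converged) ", converged" else ""))
  est <- x$estimate[!grepl("^k_pV_\\d+$", names(x$estimate))]
  if (length(est))
    cat(paste(sprintf("  %s = %.4g", names(est), unlist(est)),
              collapse = "\n"), "\n")
  invisible(x)
}
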