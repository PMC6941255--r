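#' Mechanical state of the tissue
#'
#' Bundles the tissue elastic properties and the stress-diffusion coupling
#' constants used by the mechanically-coupled growth model. Displacement
#' solves a linear-elastic, isotropic equilibrium driven by tumor cell
#' gradients; the resulting von Mises stress exponentially dampens the tumor
#' and vascular diffusion coefficients.
#'
#' Tissue properties default to G = 2100 Pa and nu = 0.45 uniformly in brain;
#' both may be supplied as fields (per-voxel) or scalars and are treated as
#' temporally invariant model inputs.
#'
#' @param grid a [make_grid()] grid.
#' @param G shear modulus in Pa, scalar or 3D field.
#' @param nu Poisson's ratio in (0, 0.5), scalar or 3D field.
#' @param lambda1 stress-diffusion coupling constant (1/Pa), >= 0.
#' @param lambda2 force coupling constant (dimensionless), fixed at 1 by
#'   default.
#' @return An object of class `mechanical_state`. The elasticity operator and
#'   its sparse factorization are cached inside the object and reused across
#'   solves (the operator depends only on the grid, G and nu).
#' @export
mechanical_state <- function(grid, G = 2100, nu = 0.45, lambda1 = 0,
                             lambda2 = 1) {
  d <- grid$dims
  if (length(G) == 1) G <- array(G, d)
  if (length(nu) == 1) nu <- array(nu, d)
  if (!identical(dim(G), d) || !identical(dim(nu), d))
    validation_error("G and nu must be scalars or fields of the grid dims")
  bm <- grid$brain_mask
  if (any(G[bm] <= 0)) validation_error("G must be positive in the brain mask")
  if (any(nu[bm] <= 0 | nu[bm] >= 0.5 - 1e-9))
    validation_error("nu must lie strictly in (0, 0.5); the incompressible limit is unsupported")
  if (lambda1 < 0) validation_error("lambda1 must be >= 0")
  structure(list(G = G, nu = nu, lambda1 = lambda1, lambda2 = lambda2,
                 cache = new.env(parent = emptyenv())),
            class = "mechanical_state")
}

# Assemble the discrete elasticity operator over brain voxels.
#
# Unknowns are the three displacement components at each brain voxel
# (column-major voxel order, component-major blocks). The operator is the
# negated left-hand side of div(G grad u_c) + d/dx_c [G/(1-2nu) div u],
# discretized with second-order central differences: the Laplacian-like term
# in flux-conservative form with harmonic-mean face shear moduli and
# zero-flux closure at the mask surface; the grad-div term in its symmetric
# (adjoint-gradient) form Dc' kappa Dc, which matches the composed central
# differences in the interior and keeps the assembled matrix symmetric
# positive definite so a sparse Cholesky factorization can be cached.
# Boundary contract: at a voxel whose face neighbour along axis k lies
# outside the brain, the normal displacement component u_k is pinned to zero
# (symmetric elimination) while tangential components keep the traction-free
# closure (slip condition, realised voxelwise by face adjacency).
#
# Returns list(A, Dc, idx, n, bc_rows): the SPD operator (solving
# A u = -lambda2 grad phi_T), the central-difference operators, full-grid
# linear indices of brain voxels, their count, and the pinned rows.
assemble_elasticity <- function(mech, grid) {
  bm <- grid$brain_mask
  d <- grid$dims
  h <- grid$spacing
  idx <- which(bm)
  n <- length(idx)
  bid <- array(0L, d)
  bid[idx] <- seq_len(n)

  # neighbour brain index (0 = outside grid or mask) per axis/direction
  nb <- vector("list", 3)
  for (ax in 1:3)
    nb[[ax]] <- list(p = shift3(bid, ax, -1, 0L)[idx],
                     m = shift3(bid, ax, +1, 0L)[idx])

  Gv <- mech$G[idx]
  kappa <- (mech$G / (1 - 2 * mech$nu))[idx]

  # central-difference operators Dc[[ax]] (n x n), zero-gradient closure
  Dc <- vector("list", 3)
  for (ax in 1:3) {
    p <- nb[[ax]]$p; m <- nb[[ax]]$m
    rows <- seq_len(n)
    ip <- ifelse(p > 0L, p, rows)   # missing neighbour -> centre value
    im <- ifelse(m > 0L, m, rows)
    w <- 1 / (2 * h[ax])
    Dc[[ax]] <- Matrix::sparseMatrix(
      i = c(rows, rows), j = c(ip, im), x = c(rep(w, n), rep(-w, n)),
      dims = c(n, n))
  }

  # flux-form div(G grad .) with harmonic-mean face G, zero flux at surface
  trip_i <- trip_j <- integer(0); trip_x <- numeric(0)
  diag_acc <- numeric(n)
  for (ax in 1:3) {
    for (side in c("p", "m")) {
      q <- nb[[ax]][[side]]
      has <- q > 0L
      rows <- which(has)
      Gf <- 2 * Gv[rows] * Gv[q[has]] / (Gv[rows] + Gv[q[has]])
      w <- Gf / h[ax]^2
      trip_i <- c(trip_i, rows)
      trip_j <- c(trip_j, q[has])
      trip_x <- c(trip_x, w)
      diag_acc[rows] <- diag_acc[rows] - w
    }
  }
  LG <- Matrix::sparseMatrix(i = c(trip_i, seq_len(n)),
                             j = c(trip_j, seq_len(n)),
                             x = c(trip_x, diag_acc), dims = c(n, n))

  K <- Matrix::Diagonal(n, kappa)
  blocks <- vector("list", 9)
  for (ci in 1:3) for (ai in 1:3) {
    B <- Matrix::t(Dc[[ci]]) %*% K %*% Dc[[ai]]
    if (ci == ai) B <- B - LG
    blocks[[(ci - 1) * 3 + ai]] <- B
  }
  A <- rbind(cbind(blocks[[1]], blocks[[2]], blocks[[3]]),
             cbind(blocks[[4]], blocks[[5]], blocks[[6]]),
             cbind(blocks[[7]], blocks[[8]], blocks[[9]]))
  A <- methods::as(A, "CsparseMatrix")

  # slip boundary: pin the normal component at mask-surface voxels
  bc_rows <- integer(0)
  for (ax in 1:3) {
    surf <- which(nb[[ax]]$p == 0L | nb[[ax]]$m == 0L)
    bc_rows <- c(bc_rows, (ax - 1L) * n + surf)
  }
  bc_rows <- sort(unique(bc_rows))
  if (length(bc_rows)) {
    Z <- Matrix::Diagonal(3 * n, x = 1)
    keep <- Matrix::Diagonal(3 * n, x = as.numeric(!(seq_len(3 * n) %in% bc_rows)))
    A <- keep %*% A %*% keep + (Z - keep)
  }
  A <- Matrix::forceSymmetric(A)
  list(A = A, Dc = Dc, idx = idx, n = n, bc_rows = bc_rows)
}

elasticity_system <- function(mech, grid) {
  cache <- mech$cache
  if (is.null(cache$sys)) {
    sys <- assemble_elasticity(mech, grid)
    sys$fact <- tryCatch(Matrix::Cholesky(sys$A, LDL = FALSE),
                         error = function(e)
      numerical_error("elasticity operator is singular or ill-conditioned: %s",
                      conditionMessage(e)))
    cache$sys <- sys
  }
  cache$sys
}

#' Solve the linear-elastic equilibrium for tissue displacement
#'
#' Solves `div(G grad u) + grad[G/(1-2 nu)] (div u) = lambda2 grad phi_T` on
#' the brain mask, with zero displacement normal to the mask surface and a
#' traction-free (slip) tangential closure. The sparse operator is assembled
#' and LU-factorized once per (grid, G, nu) and reused, so repeated solves
#' during a simulation cost one triangular solve each.
#'
#' @param phi_T tumor cell fraction field on the grid.
#' @param mech a [mechanical_state()].
#' @param grid the grid.
#' @return list with `u` (dims x 3 array, mm), and `residual` (relative
#'   equilibrium residual of the linear system).
#' @export
solve_displacement <- function(phi_T, mech, grid) {
  if (!identical(dim(phi_T), grid$dims))
    validation_error("phi_T dims do not match grid")
  sys <- elasticity_system(mech, grid)
  n <- sys$n
  phi_b <- phi_T[sys$idx]
  b <- c(as.numeric(sys$Dc[[1]] %*% phi_b),
         as.numeric(sys$Dc[[2]] %*% phi_b),
         as.numeric(sys$Dc[[3]] %*% phi_b)) * (-mech$lambda2)
  b[sys$bc_rows] <- 0
  if (all(b == 0)) {
    uvec <- numeric(3 * n)
  } else {
    uvec <- tryCatch(as.numeric(Matrix::solve(sys$fact, b)),
                     error = function(e)
                       numerical_error("displacement solve failed: %s",
                                       conditionMessage(e)))
  }
  nb <- sqrt(sum(b^2))
  resid <- if (nb > 0)
    sqrt(sum(as.numeric(sys$A %*% uvec - b)^2)) / nb else 0
  u <- array(0, c(grid$dims, 3))
  for (c3 in 1:3) {
    comp <- array(0, grid$dims)
    comp[sys$idx] <- uvec[((c3 - 1) * n + 1):(c3 * n)]
    u[, , , c3] <- comp
  }
  list(u = u, residual = resid)
}

#' Von Mises stress from a displacement field
#'
#' Computes the symmetric strain of `u` by central differences (zero-gradient
#' closure at the mask surface), forms the isotropic linear-elastic stress
#' tensor `sigma = 2 G eps + lambda_L tr(eps) I` with Lame parameter
#' `lambda_L = 2 G nu / (1 - 2 nu)`, and returns the von Mises invariant of
#' its deviatoric part. Nonnegative by construction; zero for zero or purely
#' hydrostatic strain.
#'
#' @param u displacement array (dims x 3) from [solve_displacement()].
#' @param mech a [mechanical_state()].
#' @param grid the grid.
#' @return 3D field of von Mises stress (Pa).
#' @export
von_mises_stress <- function(u, mech, grid) {
  d <- grid$dims; h <- grid$spacing; bm <- grid$brain_mask
  if (!identical(dim(u), c(d, 3L)))
    validation_error("u must be a dims x 3 array")
  gu <- vector("list", 9) # gu[[(i-1)*3+j]] = d u_j / d x_i
  for (i in 1:3) for (j in 1:3)
    gu[[(i - 1) * 3 + j]] <- central_diff(array(u[, , , j], d), i, h[i], bm)
  e11 <- gu[[1]]; e22 <- gu[[5]]; e33 <- gu[[9]]
  e12 <- 0.5 * (gu[[2]] + gu[[4]])
  e13 <- 0.5 * (gu[[3]] + gu[[7]])
  e23 <- 0.5 * (gu[[6]] + gu[[8]])
  G <- mech$G
  lamL <- 2 * G * mech$nu / (1 - 2 * mech$nu)
  tr <- e11 + e22 + e33
  s11 <- 2 * G * e11 + lamL * tr
  s22 <- 2 * G * e22 + lamL * tr
  s33 <- 2 * G * e33 + lamL * tr
  s12 <- 2 * G * e12; s13 <- 2 * G * e13; s23 <- 2 * G * e23
  vm <- array(sqrt(pmax(0, 0.5 * ((s11 - s22)^2 + (s22 - s33)^2 + (s33 - s11)^2) +
                          3 * (s12^2 + s13^2 + s23^2))), d)
  vm[!bm] <- 0
  vm
}

#' Stress-damped diffusion coefficient
#'
#' `D = D0 * exp(-lambda1 * sigma_vm)` voxelwise; applied identically to the
#' tumor and vascular diffusion coefficients.
#'
#' @param D0 undamped diffusion coefficient (mm^2/day), >= 0.
#' @param lambda1 stress-diffusion coupling (1/Pa), >= 0.
#' @param sigma_vm von Mises stress field (Pa), >= 0.
#' @return diffusion field with `0 < D <= D0` wherever `sigma_vm >= 0`.
#' @export
damp_diffusion <- function(D0, lambda1, sigma_vm) {
  if (D0 < 0) validation_error("D0 must be >= 0")
  if (lambda1 < 0) validation_error("lambda1 must be >= 0")
  D0 * exp(-lambda1 * sigma_vm)
}
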