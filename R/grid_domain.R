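#' Computational grid specification
#'
#' Defines the regular anisotropic voxel grid shared by all model components,
#' together with the brain mask that delimits the simulation domain. The
#' full-scale default (128 x 128 x 16 voxels at 0.25 x 0.25 x 1 mm) matches a
#' 32 x 32 x 16 mm^3 field of view; any dimensions are accepted. Fields are
#' defined at voxel centres and all distances are computed in physical mm.
#'
#' @param dims integer triple (nx, ny, nz).
#' @param spacing voxel spacing in mm, length-3, all strictly positive.
#' @param brain_mask logical 3D array of dimension `dims` with at least one
#'   `TRUE` voxel; `NULL` means the whole grid is brain.
#' @return An object of class `grid_spec` with elements `dims`, `spacing`,
#'   `brain_mask`.
#' @export
make_grid <- function(dims, spacing = c(0.25, 0.25, 1.0), brain_mask = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(is.na(dims)) || any(dims < 1))
    validation_error("dims must be a positive integer triple")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    validation_error("spacing must be a strictly positive length-3 vector (mm)")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dims)
  if (!is.logical(brain_mask)) brain_mask <- brain_mask != 0
  if (!identical(dim(brain_mask), dims))
    validation_error("brain_mask shape %s does not match dims %s",
                     paste(dim(brain_mask), collapse = "x"),
                     paste(dims, collapse = "x"))
  if (!any(brain_mask))
    validation_error("brain_mask has no TRUE voxel")
  structure(list(dims = dims, spacing = spacing, brain_mask = brain_mask),
            class = "grid_spec")
}

#' @export
#' @method print grid_spec
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %s voxels at %s mm, %d brain voxels\n",
              paste(x$dims, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$brain_mask)))
  invisible(x)
}

#' Time series of tumor and blood volume fraction fields
#'
#' Container for co-registered 3D maps of tumor cell volume fraction (phi_T)
#' and blood volume fraction (phi_V) at a set of measurement times (days),
#' plus per-time tumor masks. Fractions live in \[0, 1\] inside the brain mask
#' and are identically zero outside it.
#'
#' @param times strictly increasing numeric vector of measurement days.
#' @param phi_T,phi_V lists of 3D arrays, one per time.
#' @param tumor_masks optional list of logical 3D arrays, one per time.
#' @return An object of class `scalar_field_series`.
#' @export
field_series <- function(times, phi_T, phi_V, tumor_masks = NULL) {
  times <- as.numeric(times)
  if (!is.list(phi_T)) phi_T <- list(phi_T)
  if (!is.list(phi_V)) phi_V <- list(phi_V)
  if (length(phi_T) != length(times) || length(phi_V) != length(times))
    validation_error("phi_T/phi_V must have one field per time point")
  if (is.null(tumor_masks))
    tumor_masks <- lapply(phi_T, function(a) array(FALSE, dim(a)))
  structure(list(times = times, phi_T = phi_T, phi_V = phi_V,
                 tumor_masks = tumor_masks),
            class = "scalar_field_series")
}

#' @export
#' @method print scalar_field_series
print.scalar_field_series <- function(x, ...) {
  cat(sprintf("<scalar_field_series> %d time points (days %s)\n",
              length(x$times), paste(format(x$times), collapse = ", ")))
  invisible(x)
}

#' Validate a field series against its grid
#'
#' Checks the series invariants (time ordering, fraction ranges inside the
#' brain, zeros outside the brain, tumor masks nested in the brain mask) and
#' returns a report instead of throwing: each violation is a row naming the
#' field, the time index and the rule breached. The function is side-effect
#' free and idempotent.
#'
#' @param series a [field_series()].
#' @param grid a [make_grid()] grid.
#' @return A data frame with columns `field`, `time_index`, `rule`, `detail`;
#'   zero rows iff the series is valid.
#' @export
validate_series <- function(series, grid) {
  v <- list()
  add <- function(field, ti, rule, detail)
    v[[length(v) + 1]] <<- data.frame(field = field, time_index = ti,
                                      rule = rule, detail = detail,
                                      stringsAsFactors = FALSE)
  if (is.unsorted(series$times, strictly = TRUE))
    add("times", NA_integer_, "ordering", "times must be strictly increasing")
  bm <- grid$brain_mask
  for (ti in seq_along(series$times)) {
    for (fname in c("phi_T", "phi_V")) {
      f <- series[[fname]][[ti]]
      if (!identical(dim(f), grid$dims)) {
        add(fname, ti, "shape", sprintf("field dims %s != grid dims %s",
                                        paste(dim(f), collapse = "x"),
                                        paste(grid$dims, collapse = "x")))
        next
      }
      bad <- which(bm & (f < 0 | f > 1))
      if (length(bad))
        add(fname, ti, "range",
            sprintf("%d voxel(s) outside [0,1], first at linear index %d (value %.6g)",
                    length(bad), bad[1], f[bad[1]]))
      out <- which(!bm & f != 0)
      if (length(out))
        add(fname, ti, "support",
            sprintf("%d nonzero voxel(s) outside brain mask", length(out)))
    }
    tm <- series$tumor_masks[[ti]]
    if (!is.null(tm) && any(tm & !bm))
      add("tumor_mask", ti, "nesting", "tumor mask extends outside brain mask")
  }
  if (length(v) == 0)
    return(data.frame(field = character(), time_index = integer(),
                      rule = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Physical voxel coordinates
#'
#' Centre coordinates (mm) of every voxel, 0-based indexing times spacing.
#' @param grid a grid_spec.
#' @return n x 3 matrix for all voxels in column-major order.
#' @keywords internal
voxel_coords <- function(grid) {
  d <- grid$dims; h <- grid$spacing
  i <- (seq_len(d[1]) - 1) * h[1]
  j <- (seq_len(d[2]) - 1) * h[2]
  k <- (seq_len(d[3]) - 1) * h[3]
  cbind(rep(i, times = d[2] * d[3]),
        rep(rep(j, each = d[1]), times = d[3]),
        rep(k, each = d[1] * d[2]))
}

#' Ellipsoidal brain mask
#'
#' Convenience constructor for a phantom brain: an axis-aligned ellipsoid of
#' given semi-axes (mm) centred in the field of view.
#' @param dims,spacing as in [make_grid()].
#' @param semi_axes length-3 semi-axes in mm; default 90% of the half-FOV.
#' @return logical 3D array.
#' @export
ellipsoid_mask <- function(dims, spacing, semi_axes = NULL) {
  dims <- as.integer(dims)
  fov <- dims * spacing
  if (is.null(semi_axes)) semi_axes <- 0.45 * fov
  ctr <- (dims - 1) / 2 * spacing
  g <- make_grid(dims, spacing)
  xyz <- voxel_coords(g)
  r2 <- ((xyz[, 1] - ctr[1]) / semi_axes[1])^2 +
    ((xyz[, 2] - ctr[2]) / semi_axes[2])^2 +
    ((xyz[, 3] - ctr[3]) / semi_axes[3])^2
  array(r2 <= 1, dims)
}
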