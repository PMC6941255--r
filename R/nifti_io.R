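#' Write a subject directory
#'
#' One NIfTI volume per field per time point (double precision, voxel spacing
#' in the header), an integer label mask per time point (0 background,
#' 1 brain, 2 tumor), and a JSON sidecar listing times (days), the
#' radiotherapy schedule and the file map.
#'
#' @param dir output directory (created if needed).
#' @param series a [field_series()].
#' @param grid the grid.
#' @param rt_day,dose_Gy radiotherapy schedule recorded in the sidecar.
#' @param extra optional named list merged into the sidecar.
#' @return the sidecar path, invisibly.
#' @export
write_subject <- function(dir, series, grid, rt_day = 14.5, dose_Gy = 40,
                          extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- length(series$times)
  files <- list()
  for (i in seq_len(nt)) {
    fT <- sprintf("phiT_%02d.nii.gz", i)
    fV <- sprintf("phiV_%02d.nii.gz", i)
    fM <- sprintf("labels_%02d.nii.gz", i)
    wr <- function(arr, file, dt) {
      img <- RNifti::asNifti(arr)
      RNifti::pixdim(img) <- grid$spacing
      RNifti::writeNifti(img, file.path(dir, file), datatype = dt)
    }
    wr(series$phi_T[[i]], fT, "double")
    wr(series$phi_V[[i]], fV, "double")
    labels <- array(0L, grid$dims)
    labels[grid$brain_mask] <- 1L
    labels[series$tumor_masks[[i]]] <- 2L
    wr(labels, fM, "int16")
    files[[i]] <- list(phi_T = fT, phi_V = fV, labels = fM)
  }
  sidecar <- c(list(times_days = series$times,
                    rt = list(day = rt_day, dose_Gy = dose_Gy),
                    dims = grid$dims, spacing_mm = grid$spacing,
                    files = files),
               extra)
  path <- file.path(dir, "subject.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a subject directory
#'
#' Inverse of [write_subject()]: reconstructs the grid (brain mask from the
#' label volumes), the measured [field_series()] and the radiotherapy
#' schedule from the sidecar.
#'
#' @param dir subject directory containing `subject.json`.
#' @return list with `series`, `grid`, `rt` and the full `sidecar`.
#' @export
read_subject <- function(dir) {
  path <- file.path(dir, "subject.json")
  if (!file.exists(path)) validation_error("no subject.json in %s", dir)
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- as.integer(sc$dims)
  nt <- length(sc$times_days)
  rd <- function(file) {
    arr <- as.array(RNifti::readNifti(file.path(dir, file)))
    array(as.numeric(arr), dims)
  }
  phi_T <- list(); phi_V <- list(); masks <- list()
  brain <- NULL
  for (i in seq_len(nt)) {
    phi_T[[i]] <- rd(sc$files$phi_T[i])
    phi_V[[i]] <- rd(sc$files$phi_V[i])
    labels <- rd(sc$files$labels[i])
    masks[[i]] <- array(labels == 2, dims)
    b <- array(labels >= 1, dims)
    brain <- if (is.null(brain)) b else (brain | b)
  }
  grid <- make_grid(dims, as.numeric(sc$spacing_mm), brain)
  series <- field_series(sc$times_days, phi_T, phi_V, masks)
  list(series = series, grid = grid, rt = sc$rt, sidecar = sc)
}
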