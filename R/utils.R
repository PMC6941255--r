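#' @useDynLib rtforecast, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif setNames
NULL

# Shift a 3D array by one voxel along an axis, padding with `fill`.
# shift = +1 returns A[i-1] at position i (neighbour "below").
shift3 <- function(a, axis, shift, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  n <- d[axis]
  if (abs(shift) >= n) return(out)
  if (shift > 0) {
    idx_dst[[axis]] <- (shift + 1):n
    idx_src[[axis]] <- 1:(n - shift)
  } else if (shift < 0) {
    idx_dst[[axis]] <- 1:(n + shift)
    idx_src[[axis]] <- (1 - shift):n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Central difference along an axis in physical units. At voxels whose
# neighbour in a direction lies outside `mask`, the outside value is replaced
# by the centre value (zero-gradient closure), giving a one-sided estimate.
central_diff <- function(a, axis, h, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  ap <- shift3(a, axis, -1)   # value at i+1
  am <- shift3(a, axis, +1)   # value at i-1
  inp <- shift3(mask, axis, -1, fill = FALSE)
  inm <- shift3(mask, axis, +1, fill = FALSE)
  ap[!inp] <- a[!inp]
  am[!inm] <- a[!inm]
  out <- (ap - am) / (2 * h)
  out[!mask] <- 0
  out
}

# 6-connected binary dilation restricted to `within`.
dilate_mask <- function(mask, n = 1, within = NULL) {
  m <- mask
  for (i in seq_len(n)) {
    m <- m |
      shift3(m, 1, 1, FALSE) | shift3(m, 1, -1, FALSE) |
      shift3(m, 2, 1, FALSE) | shift3(m, 2, -1, FALSE) |
      shift3(m, 3, 1, FALSE) | shift3(m, 3, -1, FALSE)
  }
  if (!is.null(within)) m <- m & within
  m
}

# Largest 6-connected component of a binary 3D mask.
largest_component <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxy <- d[1] * d[2]
  idx_all <- which(mask)
  if (length(idx_all) == 0) return(mask)
  cur <- 0L
  sizes <- integer(0)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    sz <- 0L
    while (length(queue) > 0) {
      v <- queue
      queue <- integer(0)
      sz <- sz + length(v)
      k <- (v - 1L) %/% nxy
      r <- (v - 1L) %% nxy
      j <- r %/% d[1]
      i <- r %% d[1]
      for (step in list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                        c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))) {
        ii <- i + step[1]; jj <- j + step[2]; kk <- k + step[3]
        ok <- ii >= 0L & ii < d[1] & jj >= 0L & jj < d[2] & kk >= 0L & kk < d[3]
        w <- v[ok] + step[1] + step[2] * d[1] + step[3] * nxy
        w <- w[mask[w] & lab[w] == 0L]
        if (length(w)) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
      queue <- unique(queue)
    }
    sizes[cur] <- sz
  }
  best <- which.max(sizes)
  lab == best
}

validation_error <- function(msg, ...) {
  stop(structure(class = c("rtforecast_validation_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

numerical_error <- function(msg, ...) {
  stop(structure(class = c("rtforecast_numerical_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
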