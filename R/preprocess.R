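# Velocity pre-processing: eddy-current plane subtraction, neighborhood-
# median phase unwrapping, magnitude-based noise masking, and the PC-MRA
# contrast volume.

#' Correct residual eddy-current velocity offsets
#'
#' Identifies static tissue (above-floor magnitude with low temporal
#' velocity variation), fits a first-order polynomial (constant plus linear
#' terms in x, y, z) per velocity direction to the static-tissue velocities
#' of the last time frame, and subtracts the fitted plane from every frame.
#'
#' @param field \code{velocity_field}.
#' @param magnitude paired \code{magnitude_series} on the same grid.
#' @param sd_threshold static-tissue temporal velocity sd bound, m/s.
#' @param floor_fraction fraction of the 99th-percentile time-averaged
#'   magnitude below which voxels are considered background.
#' @param min_static minimum number of static voxels required; below this
#'   the correction is skipped with a warning.
#' @return corrected \code{velocity_field}.
#' @export
correct_eddy_currents <- function(field, magnitude, sd_threshold = 0.05,
                                  floor_fraction = 0.02, min_static = 100) {
  d <- dim(field$data)
  if (!all(d[1:3] == dim(magnitude$data)[1:3])) {
    stop("velocity and magnitude grids differ", call. = FALSE)
  }
  mag_mean <- apply(magnitude$data, 1:3, mean)
  p99 <- stats::quantile(mag_mean, 0.99, names = FALSE)
  above_floor <- mag_mean >= floor_fraction * p99
  nt <- d[5]
  max_sd <- array(0, d[1:3])
  for (dir in 1:3) {
    v <- field$data[, , , dir, ]
    dim(v) <- c(prod(d[1:3]), nt)
    mu <- rowMeans(v)
    sdv <- sqrt(rowSums((v - mu)^2) / max(1, nt - 1))
    max_sd <- pmax(max_sd, array(sdv, d[1:3]))
  }
  static <- above_floor & max_sd < sd_threshold
  n_static <- sum(static)
  if (n_static < min_static) {
    warning(sprintf(
      "only %d static-tissue voxels (< %d); eddy-current correction skipped",
      n_static, min_static), call. = FALSE)
    return(field)
  }
  pts <- voxel_centers(d[1:3], field$spacing)
  sidx <- which(static)
  X <- cbind(1, pts[sidx, , drop = FALSE])
  data <- field$data
  all_pts_X <- cbind(1, pts)
  for (dir in 1:3) {
    y <- data[, , , dir, nt][sidx]
    beta <- stats::lm.fit(X, y)$coefficients
    beta[is.na(beta)] <- 0
    plane <- array(all_pts_X %*% beta, d[1:3])
    for (f in seq_len(nt)) {
      data[, , , dir, f] <- data[, , , dir, f] - plane
    }
  }
  velocity_field(data, field$spacing, field$frame_dt, field$venc)
}

#' Unwrap velocity aliasing
#'
#' Two algorithms behind one interface, applied per direction and frame:
#' \describe{
#'   \item{region_grow (default)}{Quality-guided region growing: starting
#'   from the voxel of smallest speed, voxels are merged in order of
#'   ascending wrapped difference to an already-unwrapped 6-neighbor and
#'   shifted by the multiple of 2 venc that matches it. Recovers any wrap
#'   pattern -- including solid wrapped jet cores -- exactly, provided true
#'   neighbor-to-neighbor differences stay below venc.}
#'   \item{neighborhood_median}{Voxels deviating from their 3x3x3
#'   neighborhood median by more than venc are shifted by the multiple of
#'   2 venc closest to the median, iterated up to \code{max_iter} passes.
#'   Repairs isolated wraps in a smooth field but cannot detect extended
#'   wrapped regions, whose interior agrees with its own median.}
#' }
#' Both are idempotent on wrap-free fields.
#'
#' @param field \code{velocity_field} with positive venc per direction.
#' @param method unwrapping algorithm.
#' @param max_iter maximum passes (neighborhood_median only).
#' @return unwrapped \code{velocity_field}.
#' @export
unwrap_velocity <- function(field, method = c("region_grow",
                                              "neighborhood_median"),
                            max_iter = 5) {
  method <- match.arg(method)
  if (any(field$venc <= 0)) stop("venc must be positive", call. = FALSE)
  d <- dim(field$data)
  data <- field$data
  for (dir in 1:3) {
    venc <- field$venc[dir]
    for (f in seq_len(d[5])) {
      v <- data[, , , dir, f]
      if (method == "region_grow") {
        grown <- array(.unwrap_region_grow_cpp(as.numeric(v),
                                               as.integer(d[1:3]), venc),
                       d[1:3])
        # growth fixes the field up to one global multiple of 2 venc; anchor
        # it to the branch most of the measured data already lies on
        k <- round((grown - v) / (2 * venc))
        kshift <- round(stats::median(k))
        v <- grown - 2 * venc * kshift
      } else {
        for (it in seq_len(max_iter)) {
          med <- median_filter3(v)
          k <- round((med - v) / (2 * venc))
          k[abs(v - med) <= venc] <- 0
          if (!any(k != 0)) break
          v <- v + 2 * venc * k
        }
      }
      data[, , , dir, f] <- v
    }
  }
  velocity_field(data, field$spacing, field$frame_dt, field$venc)
}

#' Build the noise mask from the magnitude series
#'
#' Keeps voxels whose time-averaged magnitude reaches \code{floor_fraction}
#' of the 99th-percentile time-averaged magnitude.
#'
#' @param magnitude \code{magnitude_series}.
#' @param floor_fraction threshold fraction in (0, 1).
#' @return logical 3D array marking kept voxels, with spacing attribute.
#' @export
noise_mask <- function(magnitude, floor_fraction = 0.1) {
  if (floor_fraction <= 0 || floor_fraction >= 1) {
    stop("floor_fraction must lie in (0, 1)", call. = FALSE)
  }
  mag_mean <- apply(magnitude$data, 1:3, mean)
  if (all(mag_mean == 0)) {
    stop("magnitude is identically zero; empty noise mask", call. = FALSE)
  }
  thr <- floor_fraction * stats::quantile(mag_mean, 0.99, names = FALSE)
  keep <- mag_mean >= thr
  attr(keep, "spacing") <- magnitude$spacing
  keep
}

#' Zero velocities outside a noise mask
#'
#' @param field \code{velocity_field}.
#' @param mask logical 3D array (e.g. from \code{\link{noise_mask}}).
#' @return masked \code{velocity_field}.
#' @export
mask_velocity <- function(field, mask) {
  d <- dim(field$data)
  data <- field$data
  keep <- array(as.logical(mask), d[1:3])
  for (dir in 1:3) for (f in seq_len(d[5])) {
    v <- data[, , , dir, f]
    v[!keep] <- 0
    data[, , , dir, f] <- v
  }
  velocity_field(data, field$spacing, field$frame_dt, field$venc)
}

#' Compute the time-averaged PC-MRA volume
#'
#' Per frame, the voxelwise product of the magnitude image with the
#' velocity magnitude; the result is the mean over all frames.
#'
#' @param field \code{velocity_field}.
#' @param magnitude paired \code{magnitude_series}.
#' @return \code{pcmra_volume}.
#' @export
compute_pcmra <- function(field, magnitude) {
  d <- dim(field$data)
  dm <- dim(magnitude$data)
  if (!all(d[1:3] == dm[1:3]) || d[5] != dm[4]) {
    stop("velocity and magnitude grids/frames differ", call. = FALSE)
  }
  acc <- array(0, d[1:3])
  for (f in seq_len(d[5])) {
    sp <- sqrt(field$data[, , , 1, f]^2 + field$data[, , , 2, f]^2 +
                 field$data[, , , 3, f]^2)
    acc <- acc + magnitude$data[, , , f] * sp
  }
  pcmra_volume(acc / d[5], field$spacing)
}

#' Run the full pre-processing chain
#'
#' Eddy-current correction, velocity unwrapping, noise masking and PC-MRA
#' computation, in that order.
#'
#' @param field measured \code{velocity_field}.
#' @param magnitude paired \code{magnitude_series}.
#' @param floor_fraction noise-mask threshold fraction.
#' @param sd_threshold static-tissue velocity sd bound, m/s.
#' @return list(field, mask, pcmra): the corrected and masked field, the
#'   noise mask, and the time-averaged PC-MRA volume.
#' @export
preprocess_subject <- function(field, magnitude, floor_fraction = 0.1,
                               sd_threshold = 0.05) {
  field <- correct_eddy_currents(field, magnitude, sd_threshold = sd_threshold)
  field <- unwrap_velocity(field)
  mask <- noise_mask(magnitude, floor_fraction)
  field <- mask_velocity(field, mask)
  pcmra <- compute_pcmra(field, magnitude)
  list(field = field, mask = mask, pcmra = pcmra)
}
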