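# Peak-systolic haemodynamics: peak/mean velocity, the inward-normal
# spline WSS estimator, and viscous energy loss from the dissipation
# function. Frames are 1-based (R convention).

#' Find the peak-systolic frame
#'
#' The frame with the highest velocity magnitude averaged over the
#' segmentation; ties break toward the earlier frame.
#'
#' @param field \code{velocity_field}.
#' @param mask \code{aorta_mask}.
#' @return integer frame index (1-based).
#' @export
find_peak_systole <- function(field, mask) {
  if (!any(mask$data)) stop("mask is empty", call. = FALSE)
  nt <- n_frames(field)
  means <- vapply(seq_len(nt), function(f) {
    fr <- field$data[, , , , f]
    dim(fr) <- dim(field$data)[1:4]
    mean(speed_volume(fr)[mask$data])
  }, 0)
  which.max(means)
}

#' Median-filter a single-frame velocity volume
#'
#' Per-component 3x3x3 median with reflected edge padding, applied to the
#' peak-systolic frame to suppress isolated velocity noise.
#'
#' @param frame_arr array \code{c(nx, ny, nz, 3)}.
#' @return filtered array of the same shape.
#' @export
median_filter_peak <- function(frame_arr) {
  for (dir in 1:3) {
    frame_arr[, , , dir] <- median_filter3(frame_arr[, , , dir])
  }
  frame_arr
}

#' Peak velocity within a region of interest
#'
#' @param frame_arr single-frame velocity array \code{c(nx, ny, nz, 3)}
#'   (median-filter beforehand via \code{\link{median_filter_peak}} when
#'   following the standard pipeline).
#' @param mask \code{aorta_mask}.
#' @param roi optional logical 3D sub-mask of \code{mask}.
#' @return peak speed in m/s, with attribute \code{position} (voxel index
#'   of the maximum).
#' @export
peak_velocity <- function(frame_arr, mask, roi = NULL) {
  keep <- mask$data
  if (!is.null(roi)) {
    roi <- array(as.logical(roi), dim(keep))
    if (any(roi & !mask$data)) {
      stop("roi must be a subset of the mask", call. = FALSE)
    }
    keep <- roi
  }
  if (!any(keep)) stop("empty region of interest", call. = FALSE)
  sp <- speed_volume(frame_arr)
  vals <- sp[keep]
  pk <- max(vals)
  pos <- which(keep)[which.max(vals)]
  structure(pk, position = arrayInd(pos, dim(sp))[1, ])
}

#' Mean velocity over the segmentation
#'
#' @inheritParams peak_velocity
#' @return mean speed in m/s.
#' @export
mean_velocity <- function(frame_arr, mask) {
  if (!any(mask$data)) stop("mask is empty", call. = FALSE)
  mean(speed_volume(frame_arr)[mask$data])
}

#' Wall shear stress by the rotated inward-normal spline method
#'
#' Per wall point the axis system is rotated so the local z-axis aligns
#' with the outward normal. The two in-plane velocity components are
#' sampled (trilinear) at three equidistant points along the inward normal
#' spanning one local radius -- the wall point itself, where the velocity
#' is forced to zero, and depths R/2 and R. The interpolating quadratic
#' through the three samples (the unique "spline" a 3-point fit admits)
#' gives the wall-normal velocity derivative analytically at the wall;
#' multiplication with viscosity and rotation back yields the 3D WSS
#' vector, tangential by construction.
#'
#' @param frame_arr single-frame velocity array \code{c(nx, ny, nz, 3)}.
#' @param wall \code{wall_points} from \code{\link{extract_wall}}.
#' @param mu viscosity (cP or \code{\link{viscosity}}).
#' @param mask optional \code{aorta_mask}; sample points that fall outside
#'   it flag their wall point, which is then excluded from the mean.
#' @return tibble of class \code{wss_map}: wall columns plus wssx, wssy,
#'   wssz, wss_mag (Pa) and excluded; attribute \code{mean_wss} (Pa).
#' @export
compute_wss <- function(frame_arr, wall, mu = viscosity(3.2), mask = NULL) {
  mu <- as_viscosity(mu)
  if (any(wall$radius <= 0)) stop("wall radii must be positive", call. = FALSE)
  sp <- attr(wall, "spacing")
  n <- cbind(wall$nx, wall$ny, wall$nz)
  p <- cbind(wall$x, wall$y, wall$z)

  # orthonormal tangent basis per point
  a <- matrix(rep(c(1, 0, 0), nrow(n)), ncol = 3, byrow = TRUE)
  swap <- abs(n[, 1]) > 0.9
  a[swap, ] <- matrix(rep(c(0, 1, 0), sum(swap)), ncol = 3, byrow = TRUE)
  t1 <- cbind(n[, 2] * a[, 3] - n[, 3] * a[, 2],
              n[, 3] * a[, 1] - n[, 1] * a[, 3],
              n[, 1] * a[, 2] - n[, 2] * a[, 1])
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(n[, 2] * t1[, 3] - n[, 3] * t1[, 2],
              n[, 3] * t1[, 1] - n[, 1] * t1[, 3],
              n[, 1] * t1[, 2] - n[, 2] * t1[, 1])

  sample_v <- function(q) {
    cbind(trilinear(frame_arr[, , , 1], q, sp),
          trilinear(frame_arr[, , , 2], q, sp),
          trilinear(frame_arr[, , , 3], q, sp))
  }
  R <- wall$radius
  q1 <- p - n * (R / 2)
  q2 <- p - n * R
  v1 <- sample_v(q1)
  v2 <- sample_v(q2)

  outside <- rep(FALSE, nrow(p))
  if (!is.null(mask)) {
    mvol <- array(as.numeric(mask$data), dim(mask$data))
    outside <- trilinear(mvol, q1, sp, outside = 0) < 0.25 |
      trilinear(mvol, q2, sp, outside = 0) < 0.25
  }
  # inlet/outlet cut planes are not vessel wall: blood crosses them, so
  # points with dominantly through-plane flow at depth R/2 are excluded
  # from the map statistics
  vmag1 <- sqrt(rowSums(v1^2))
  through <- abs(rowSums(v1 * n)) > 0.5 * vmag1 & vmag1 > 1e-9

  R_m <- R / 1000
  # quadratic through (0, 0), (R/2, v1), (R, v2): slope at wall = (4 v1 - v2) / R
  a1 <- (4 * rowSums(v1 * t1) - rowSums(v2 * t1)) / R_m
  a2 <- (4 * rowSums(v1 * t2) - rowSums(v2 * t2)) / R_m
  wss <- mu$pa_s * (a1 * t1 + a2 * t2)
  # discard any numerical normal component; shear is tangential
  wn <- rowSums(wss * n)
  wss <- wss - wn * n

  excluded <- wall$flagged | outside | through
  mag <- sqrt(rowSums(wss^2))
  out <- wall
  out$wssx <- wss[, 1]
  out$wssy <- wss[, 2]
  out$wssz <- wss[, 3]
  out$wss_mag <- mag
  out$excluded <- excluded
  attr(out, "mean_wss") <- mean(mag[!excluded])
  attr(out, "mu_cP") <- mu$cP
  class(out) <- unique(c("wss_map", class(out)))
  out
}

# Masked partial derivative along one axis: central differences where both
# neighbors are in the mask, second-order one-sided at the mask boundary,
# first-order where only one interior neighbor exists, 0 when isolated.
gradient_masked <- function(vol, mask, spacing, axis) {
  h <- spacing[axis]
  sh <- function(a, k) {
    shift3(a, -k * (axis == 1), -k * (axis == 2), -k * (axis == 3), fill = 0)
  }
  shm <- function(k) {
    shift3(mask, -k * (axis == 1), -k * (axis == 2), -k * (axis == 3),
           fill = FALSE)
  }
  vp <- sh(vol, 1); vm <- sh(vol, -1)
  vpp <- sh(vol, 2); vmm <- sh(vol, -2)
  mp <- shm(1); mm <- shm(-1); mpp <- shm(2); mmm <- shm(-2)

  g <- array(0, dim(vol))
  central <- mask & mp & mm
  g[central] <- ((vp - vm) / (2 * h))[central]
  fwd2 <- mask & !mm & mp & mpp
  g[fwd2] <- ((-3 * vol + 4 * vp - vpp) / (2 * h))[fwd2]
  fwd1 <- mask & !mm & mp & !mpp
  g[fwd1] <- ((vp - vol) / h)[fwd1]
  bwd2 <- mask & !mp & mm & mmm
  g[bwd2] <- ((3 * vol - 4 * vm + vmm) / (2 * h))[bwd2]
  bwd1 <- mask & !mp & mm & !mmm
  g[bwd1] <- ((vol - vm) / h)[bwd1]
  g
}

#' Viscous energy loss over the segmentation
#'
#' Computes first-order spatial gradients of the three velocity components
#' (central differences, one-sided at the mask boundary), evaluates the
#' incompressible-flow dissipation function per voxel, and integrates over
#' the segmentation: EL = mu * sum(Phi) * voxel volume, reported in mW.
#' The -(2/3)(div v)^2 compressibility term is retained by default since
#' measured fields are not divergence-free.
#'
#' @param frame_arr single-frame velocity array \code{c(nx, ny, nz, 3)}.
#' @param mask \code{aorta_mask}.
#' @param mu viscosity (cP or \code{\link{viscosity}}).
#' @param compressibility include the -(2/3)(div v)^2 term.
#' @return object of class \code{el_map}: list with \code{density} (W/m^3,
#'   zero outside the mask), \code{total_el} (mW), \code{spacing},
#'   \code{mask}.
#' @export
compute_energy_loss <- function(frame_arr, mask, mu = viscosity(3.2),
                                compressibility = TRUE) {
  mu <- as_viscosity(mu)
  m <- mask$data
  if (!any(m)) stop("mask is empty", call. = FALSE)
  sp_m <- mask$spacing / 1000 # gradients per meter
  g <- array(0, c(dim(m), 3, 3)) # [., ., ., component, axis]
  for (comp in 1:3) for (ax in 1:3) {
    g[, , , comp, ax] <- gradient_masked(frame_arr[, , , comp], m, sp_m, ax)
  }
  phi <- 2 * (g[, , , 1, 1]^2 + g[, , , 2, 2]^2 + g[, , , 3, 3]^2) +
    (g[, , , 1, 2] + g[, , , 2, 1])^2 +
    (g[, , , 1, 3] + g[, , , 3, 1])^2 +
    (g[, , , 2, 3] + g[, , , 3, 2])^2
  if (compressibility) {
    divv <- g[, , , 1, 1] + g[, , , 2, 2] + g[, , , 3, 3]
    phi <- phi - (2 / 3) * divv^2
  }
  phi <- pmax(phi, 0)
  phi[!m] <- 0
  vox_m3 <- mask$voxel_volume * 1e-9
  total <- mu$pa_s * sum(phi[m]) * vox_m3 * 1000 # mW
  structure(
    list(density = mu$pa_s * phi, total_el = total, spacing = mask$spacing,
         mask = m, mu_cP = mu$cP),
    class = "el_map"
  )
}

#' @export
print.el_map <- function(x, ...) {
  cat(sprintf("<el_map> total viscous energy loss %.3f mW over %d voxels\n",
              x$total_el, sum(x$mask)))
  invisible(x)
}

#' Peak-systolic haemodynamic summary of one subject
#'
#' Selects the peak-systolic frame, median-filters it, and computes the
#' four summary metrics: peak velocity, mean velocity, mean |WSS| and
#' viscous energy loss.
#'
#' @param field corrected \code{velocity_field}.
#' @param mask \code{aorta_mask}.
#' @param wall optional \code{wall_points}; extracted from the mask when
#'   missing.
#' @param mu viscosity (cP or \code{\link{viscosity}}); 3.2 cP by default.
#' @param roi optional peak-velocity region of interest (sub-mask).
#' @return one-row tibble: peak_velocity, mean_velocity, mean_wss,
#'   energy_loss, peak_frame, mu_cP; attributes \code{wss_map},
#'   \code{el_map} and \code{peak_frame_arr} carry the full maps.
#' @export
summarize_hemodynamics <- function(field, mask, wall = NULL,
                                   mu = viscosity(3.2), roi = NULL) {
  mu <- as_viscosity(mu)
  if (is.null(wall)) wall <- extract_wall(mask)
  pf <- find_peak_systole(field, mask)
  frame_arr <- field$data[, , , , pf, drop = TRUE]
  dim(frame_arr) <- dim(field$data)[1:4]
  frame_arr <- median_filter_peak(frame_arr)
  pk <- peak_velocity(frame_arr, mask, roi)
  mv <- mean_velocity(frame_arr, mask)
  wss <- compute_wss(frame_arr, wall, mu, mask = mask)
  el <- compute_energy_loss(frame_arr, mask, mu)
  out <- tibble::tibble(
    peak_velocity = as.numeric(pk),
    mean_velocity = mv,
    mean_wss = attr(wss, "mean_wss"),
    energy_loss = el$total_el,
    peak_frame = pf,
    mu_cP = mu$cP
  )
  attr(out, "wss_map") <- wss
  attr(out, "el_map") <- el
  attr(out, "peak_frame_arr") <- frame_arr
  out
}
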