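# Segmentation of the ascending aorta from the time-averaged PC-MRA, and
# wall-point extraction with outward normals and local radii.

#' Segment the vessel lumen from a PC-MRA volume
#'
#' Deterministic threshold surrogate for expert segmentation: voxels at or
#' above \code{threshold_fraction} of the 99th-percentile PC-MRA intensity,
#' optionally restricted to an axial band, largest 26-connected component,
#' followed by one morphological closing pass.
#'
#' @param pcmra \code{pcmra_volume}.
#' @param threshold_fraction fraction in (0, 1).
#' @param keep_band optional integer range \code{c(z_lo, z_hi)} of axial
#'   slice indices to retain (anatomically, annulus to brachiocephalic
#'   artery); default keeps the full volume.
#' @param vessel_support optional logical 3D array of magnitude-supported
#'   vessel voxels (e.g. from \code{\link{noise_mask}}). The thresholded
#'   component then grows iteratively into this support, which recovers the
#'   slow near-wall shell the velocity-weighted PC-MRA under-represents —
#'   the same role the magnitude image plays for a human reader placing
#'   the wall.
#' @return \code{aorta_mask}.
#' @export
segment_vessel <- function(pcmra, threshold_fraction = 0.2, keep_band = NULL,
                           vessel_support = NULL) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must lie in (0, 1)", call. = FALSE)
  }
  thr <- threshold_fraction * stats::quantile(pcmra$data, 0.99, names = FALSE)
  mask <- pcmra$data >= thr & pcmra$data > 0
  if (!is.null(keep_band)) {
    d <- dim(mask)
    lo <- max(1L, keep_band[1])
    hi <- min(d[3], keep_band[2])
    keep_z <- if (lo <= hi) lo:hi else integer(0)
    drop <- setdiff(seq_len(d[3]), keep_z)
    if (length(drop)) mask[, , drop] <- FALSE
  }
  if (!any(mask)) {
    stop(sprintf("segmentation empty at threshold_fraction = %g (threshold %g)",
                 threshold_fraction, thr), call. = FALSE)
  }
  mask <- largest_component(mask, connectivity = 26)
  mask <- close3(mask)
  mask <- largest_component(mask, connectivity = 26)
  if (!is.null(vessel_support)) {
    support <- array(as.logical(vessel_support), dim(mask))
    if (!is.null(keep_band)) {
      drop <- setdiff(seq_len(dim(mask)[3]), keep_z)
      if (length(drop)) support[, , drop] <- FALSE
    }
    for (i in 1:10) {
      grown <- dilate3(mask) & support
      if (identical(grown, mask)) break
      mask <- grown
    }
    mask <- largest_component(mask, connectivity = 26)
  }
  aorta_mask(mask, pcmra$spacing)
}

#' Extract wall points, outward normals and local radii from a mask
#'
#' Wall points originate at inside voxels having at least one outside
#' 6-neighbor. Outward normals are the negated, normalized gradient of a
#' Gaussian-smoothed (sigma = 1 voxel) inside-indicator. Each point is then
#' projected onto the 0.5 level of that smoothed indicator along its normal
#' (shift capped at one voxel) so that points sit on the lumen surface
#' rather than at voxel centers. The local radius is the maximum of the
#' Euclidean distance transform along the inward-normal ray (the maximal
#' inscribed distance at the medial point of that ray).
#'
#' @param mask \code{aorta_mask}.
#' @return tibble of class \code{wall_points} with columns x, y, z (mm),
#'   nx, ny, nz (outward unit normal), radius (mm), area (mm^2 surface
#'   patch estimate) and flagged (thin-wall/degenerate points).
#' @export
extract_wall <- function(mask) {
  m <- mask$data
  sp <- mask$spacing
  d <- dim(m)
  outside6 <- array(FALSE, d)
  off6 <- neighbor_offsets(6)
  for (i in seq_len(nrow(off6))) {
    outside6 <- outside6 | !shift3(m, off6[i, 1], off6[i, 2], off6[i, 3],
                                   fill = FALSE)
  }
  wall_vox <- m & outside6
  if (!any(wall_vox)) stop("mask has no wall voxels", call. = FALSE)
  idx <- arrayInd(which(wall_vox), d)
  p0 <- sweep(idx - 1, 2, sp, "*")

  ind <- gauss_smooth3(array(as.numeric(m), d), sigma = 1)
  grad <- vector("list", 3)
  for (ax in 1:3) {
    hi <- shift3(ind, -(ax == 1), -(ax == 2), -(ax == 3))
    lo <- shift3(ind, (ax == 1), (ax == 2), (ax == 3))
    grad[[ax]] <- (hi - lo) / (2 * sp[ax])
  }
  g <- cbind(trilinear(grad[[1]], p0, sp), trilinear(grad[[2]], p0, sp),
             trilinear(grad[[3]], p0, sp))
  gn <- sqrt(rowSums(g^2))
  degen <- gn < 1e-9
  g[degen, ] <- matrix(rep(c(1, 0, 0), sum(degen)), ncol = 3, byrow = TRUE)
  gn[degen] <- 1
  normals <- -g / gn # indicator increases inward; outward is the negation

  # project each point to the 0.5-crossing of the smoothed indicator along
  # its normal (bisection over +-1 voxel)
  hstep <- min(sp)
  tlo <- rep(-hstep, nrow(p0))
  thi <- rep(hstep, nrow(p0))
  f_at <- function(t) trilinear(ind, p0 + normals * t, sp, outside = 0) - 0.5
  flo <- f_at(tlo)
  fhi <- f_at(thi)
  bracketed <- flo > 0 & fhi < 0
  tsol <- rep(0, nrow(p0))
  if (any(bracketed)) {
    lo <- tlo
    hi <- thi
    for (it in 1:20) {
      mid <- (lo + hi) / 2
      fm <- f_at(mid)
      up <- fm > 0
      lo <- ifelse(bracketed & up, mid, lo)
      hi <- ifelse(bracketed & !up, mid, hi)
    }
    tsol[bracketed] <- ((lo + hi) / 2)[bracketed]
  }
  pts <- p0 + normals * tsol

  edt <- distance_transform3(m, sp)
  step <- min(sp) / 2
  max_len <- max(edt) * 2.5 + 2 * max(sp)
  dseq <- seq(0, max_len, by = step)
  nw <- nrow(pts)
  radius <- rep(0, nw)
  inside_ray <- rep(TRUE, nw)
  for (dd in dseq) {
    q <- pts - normals * dd
    ev <- trilinear(edt, q, sp, outside = 0)
    inmask <- trilinear(array(as.numeric(m), d), q, sp, outside = 0) > 0.25
    inside_ray <- inside_ray & (inmask | dd <= min(sp)) # allow the first steps
    radius <- ifelse(inside_ray, pmax(radius, ev), radius)
  }
  thin <- radius < 1.5 * min(sp)
  radius <- pmax(radius, step)

  # surface patch area: voxel cross-section projected onto the tangent plane
  area <- abs(normals[, 1]) * sp[2] * sp[3] +
    abs(normals[, 2]) * sp[1] * sp[3] +
    abs(normals[, 3]) * sp[1] * sp[2]

  if (any(thin)) {
    warning(sprintf("%d wall points sit on thin (< 3 voxel) structures; flagged",
                    sum(thin)), call. = FALSE)
  }
  out <- tibble::tibble(
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    nx = normals[, 1], ny = normals[, 2], nz = normals[, 3],
    radius = radius, area = area, flagged = thin | degen
  )
  attr(out, "spacing") <- sp
  class(out) <- c("wall_points", class(out))
  out
}
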