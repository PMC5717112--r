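# Shared ascending-aorta geometry: rigid registration of all subject masks
# to a median-volume reference, consensus shared mask, affine mapping of
# per-subject value maps with nearest-neighbour interpolation, and
# cohort-averaged maps.

# Affine transforms are 4x4 matrices acting on mm coordinates (row vectors
# via apply_affine). Rigid parameters: c(tx, ty, tz, rx, ry, rz) with
# rotations (radians) about the moving mask centroid.

apply_affine <- function(T, pts) {
  sweep(pts %*% t(T[1:3, 1:3]), 2, T[1:3, 4], "+")
}

rigid_to_affine <- function(par, center) {
  R <- euler_matrix(par[4], par[5], par[6])
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- center - R %*% center + par[1:3]
  T
}

mask_points <- function(mask) {
  idx <- arrayInd(which(mask$data), dim(mask$data))
  sweep(idx - 1, 2, mask$spacing, "*")
}

# Symmetric soft overlap objective: reference intensity at the transformed
# moving points plus moving intensity at the back-transformed reference
# points, normalized by the total voxel count. Counting both directions
# stops an affine fit from shrinking the moving mask into the reference
# interior (a one-sided overlap would reward that collapse).
overlap_objective <- function(ref_vol, ref_spacing, moving_vol,
                              moving_spacing, moving_pts, ref_pts) {
  denom <- nrow(moving_pts) + nrow(ref_pts)
  function(T) {
    fwd <- sum(trilinear(ref_vol, apply_affine(T, moving_pts), ref_spacing,
                         outside = 0))
    bwd <- sum(trilinear(moving_vol, apply_affine(solve(T), ref_pts),
                         moving_spacing, outside = 0))
    (fwd + bwd) / denom
  }
}

# Binary Dice between the reference mask and the moving mask resampled
# onto the reference grid (nearest neighbour through the inverse).
binary_dice <- function(T, moving, reference) {
  d <- dim(reference$data)
  ref_pts <- voxel_centers(d, reference$spacing)
  p <- apply_affine(solve(T), ref_pts)
  di <- dim(moving$data)
  pi_ <- round(sweep(p, 2, moving$spacing, "/")) + 1
  ok <- pi_[, 1] >= 1 & pi_[, 1] <= di[1] & pi_[, 2] >= 1 &
    pi_[, 2] <= di[2] & pi_[, 3] >= 1 & pi_[, 3] <= di[3]
  movR <- rep(FALSE, nrow(ref_pts))
  movR[ok] <- moving$data[pi_[ok, , drop = FALSE]]
  2 * sum(movR & reference$data) / (sum(movR) + sum(reference$data))
}

#' Register one mask to another
#'
#' Maximizes the (soft) Dice overlap between the transformed moving mask
#' and the reference by Nelder-Mead over rigid (6) or affine (12)
#' parameters, with deterministic multi-start.
#'
#' @param moving,reference \code{aorta_mask} objects.
#' @param type "rigid" or "affine"; affine is initialized from a rigid fit.
#' @param init optional initial 4x4 transform (affine stage).
#' @param n_starts number of deterministic starts (identity plus seeded
#'   perturbations).
#' @param seed seed for the perturbation starts.
#' @param lambda minimal-displacement regularization weight (per mm^2 of
#'   mean squared point displacement). Mask overlap is blind to rotations
#'   about the axis of a near-tubular mask; the penalty selects the
#'   least-motion member of that otherwise flat solution family without
#'   materially biasing genuine alignment.
#' @return list(transform = 4x4 matrix moving -> reference mm coordinates,
#'   dice = achieved binary Dice).
#' @export
register_masks <- function(moving, reference, type = c("rigid", "affine"),
                           init = NULL, n_starts = 3, seed = 1L,
                           lambda = 5e-4) {
  type <- match.arg(type)
  mpts <- mask_points(moving)
  rpts <- mask_points(reference)
  ref_vol <- array(as.numeric(reference$data), dim(reference$data))
  mov_vol <- array(as.numeric(moving$data), dim(moving$data))
  raw_obj <- overlap_objective(ref_vol, reference$spacing, mov_vol,
                               moving$spacing, mpts, rpts)
  obj <- function(T) {
    disp <- apply_affine(T, mpts) - mpts
    raw_obj(T) - lambda * mean(rowSums(disp^2))
  }
  center <- colMeans(mpts)

  if (type == "rigid") {
    fn <- function(par) -obj(rigid_to_affine(par, center))
    starts <- list(rep(0, 6))
    if (n_starts > 1) {
      pert <- with_seed(seed, lapply(seq_len(n_starts - 1), function(i) {
        c(stats::rnorm(3, 0, 2), stats::rnorm(3, 0, 3 * pi / 180))
      }))
      starts <- c(starts, pert)
    }
    best <- NULL
    for (s in starts) {
      fit <- stats::optim(s, fn, method = "Nelder-Mead",
                          control = list(maxit = 600, reltol = 1e-8,
                                         parscale = c(1, 1, 1, 0.02, 0.02, 0.02)))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    T <- rigid_to_affine(best$par, center)
  } else {
    if (is.null(init)) {
      init <- register_masks(moving, reference, "rigid",
                             n_starts = n_starts, seed = seed,
                             lambda = lambda)$transform
    }
    # parameterize as a perturbation of the rigid initialization
    par_to_T <- function(par) {
      D <- diag(4)
      D[1:3, 1:3] <- diag(3) + matrix(par[1:9], 3, 3)
      D[1:3, 4] <- par[10:12]
      Tc <- diag(4)
      Tc[1:3, 4] <- -center
      Tci <- diag(4)
      Tci[1:3, 4] <- center
      init %*% Tci %*% D %*% Tc
    }
    fn <- function(par) -obj(par_to_T(par))
    fit <- stats::optim(rep(0, 12), fn, method = "Nelder-Mead",
                        control = list(maxit = 1200, reltol = 1e-8,
                                       parscale = c(rep(0.02, 9), rep(1, 3))))
    T <- par_to_T(fit$par)
  }

  list(transform = T, dice = binary_dice(T, moving, reference))
}

#' Build the shared ascending-aorta geometry
#'
#' The reference is the mask of median volume (ties break toward the lower
#' subject index). Every other mask is rigidly registered to it; the
#' shared mask keeps voxels covered by at least \code{inclusion_fraction}
#' of the registered masks (largest connected component).
#'
#' @param masks list of \code{aorta_mask} objects (>= 2).
#' @param inclusion_fraction coverage fraction in (0, 1].
#' @param seed registration multi-start seed.
#' @return object of class \code{shared_geometry}: list(mask, wall,
#'   transforms = list of per-subject rigid 4x4 matrices, dice = per-subject
#'   Dice, inclusion_fraction, reference_index).
#' @export
build_shared_geometry <- function(masks, inclusion_fraction = 0.6, seed = 1L) {
  n <- length(masks)
  if (n < 2) stop("need at least two masks", call. = FALSE)
  vols <- vapply(masks, function(m) sum(m$data) * m$voxel_volume, 0)
  ord <- order(vols, seq_len(n)) # stable: volume, then index
  ref_i <- ord[floor((n + 1) / 2)]
  ref <- masks[[ref_i]]

  transforms <- vector("list", n)
  dice <- numeric(n)
  d <- dim(ref$data)
  coverage <- array(0, d)
  ref_pts <- voxel_centers(d, ref$spacing)
  for (i in seq_len(n)) {
    if (i == ref_i) {
      transforms[[i]] <- diag(4)
      dice[i] <- 1
    } else {
      fit <- register_masks(masks[[i]], ref, "rigid",
                            seed = derive_seed(seed, i))
      transforms[[i]] <- fit$transform
      dice[i] <- fit$dice
    }
    # resample subject mask onto the reference grid (nearest neighbour)
    Ti <- solve(transforms[[i]])
    p <- apply_affine(Ti, ref_pts)
    di <- dim(masks[[i]]$data)
    pi_ <- round(sweep(p, 2, masks[[i]]$spacing, "/")) + 1
    ok <- pi_[, 1] >= 1 & pi_[, 1] <= di[1] & pi_[, 2] >= 1 &
      pi_[, 2] <= di[2] & pi_[, 3] >= 1 & pi_[, 3] <= di[3]
    hit <- rep(FALSE, nrow(ref_pts))
    hit[ok] <- masks[[i]]$data[pi_[ok, , drop = FALSE]]
    coverage <- coverage + array(hit, d)
  }
  shared <- coverage / n >= inclusion_fraction
  if (!any(shared)) {
    stop("shared mask is empty; lower inclusion_fraction", call. = FALSE)
  }
  shared <- largest_component(shared, 26)
  shared_mask <- aorta_mask(shared, ref$spacing)
  structure(
    list(mask = shared_mask, wall = extract_wall(shared_mask),
         transforms = transforms, dice = dice,
         inclusion_fraction = inclusion_fraction, reference_index = ref_i),
    class = "shared_geometry"
  )
}

#' @export
print.shared_geometry <- function(x, ...) {
  cat(sprintf(
    "<shared_geometry> %d voxels, %d wall points, %d subjects (reference #%d, inclusion >= %.0f%%)\n",
    sum(x$mask$data), nrow(x$wall), length(x$transforms),
    x$reference_index, 100 * x$inclusion_fraction))
  invisible(x)
}

#' Map one subject's values into the shared geometry
#'
#' Registers the subject mask to the shared mask with an affine transform
#' (initialized from the build-stage rigid transform when available) and
#' pulls values by nearest-neighbour interpolation. Shared locations
#' farther than two voxels from any subject sample are marked missing (NA).
#'
#' @param values for \code{domain = "volume"}: a 3D array on the subject
#'   grid; for \code{domain = "wall"}: a numeric vector over the rows of
#'   \code{wall}.
#' @param mask subject \code{aorta_mask}.
#' @param shared \code{shared_geometry}.
#' @param domain "volume" or "wall".
#' @param wall subject \code{wall_points} (domain = "wall").
#' @param init optional initial 4x4 transform for the affine registration.
#' @param min_dice subjects whose affine Dice falls below this are rejected
#'   with an error of class \code{aortaflow_registration_error}.
#' @param seed registration seed.
#' @param fit optional precomputed registration (list with
#'   \code{transform} and \code{dice}, as returned by
#'   \code{\link{register_masks}}); skips the affine registration, so one
#'   subject registration can be reused across its velocity, WSS and EL
#'   maps.
#' @return numeric vector of values over the shared locations (shared mask
#'   voxels in array order for "volume", shared wall rows for "wall"),
#'   NA where missing; attributes \code{transform} and \code{dice}.
#' @export
map_subject <- function(values, mask, shared, domain = c("volume", "wall"),
                        wall = NULL, init = NULL, min_dice = 0.5, seed = 1L,
                        fit = NULL) {
  domain <- match.arg(domain)
  if (is.null(fit)) {
    fit <- register_masks(mask, shared$mask, "affine", init = init, seed = seed)
  }
  if (fit$dice < min_dice) {
    stop(structure(
      class = c("aortaflow_registration_error", "error", "condition"),
      list(message = sprintf("registration Dice %.2f below %.2f; subject excluded",
                             fit$dice, min_dice),
           call = NULL)))
  }
  T <- fit$transform
  sp_sub <- mask$spacing
  max_dist <- 2 * mean(sp_sub)

  if (domain == "volume") {
    stopifnot(length(dim(values)) == 3)
    shared_idx <- which(shared$mask$data)
    q <- sweep(arrayInd(shared_idx, dim(shared$mask$data)) - 1, 2,
               shared$mask$spacing, "*")
    p <- apply_affine(solve(T), q)
    di <- dim(mask$data)
    pi_ <- round(sweep(p, 2, sp_sub, "/")) + 1
    ok <- pi_[, 1] >= 1 & pi_[, 1] <= di[1] & pi_[, 2] >= 1 &
      pi_[, 2] <= di[2] & pi_[, 3] >= 1 & pi_[, 3] <= di[3]
    out <- rep(NA_real_, length(shared_idx))
    inmask <- rep(FALSE, length(shared_idx))
    inmask[ok] <- mask$data[pi_[ok, , drop = FALSE]]
    out[inmask] <- values[pi_[inmask, , drop = FALSE]]
    # near-miss recovery: points just outside the subject mask take the
    # nearest in-mask voxel within the distance cap
    miss <- which(ok & !inmask)
    if (length(miss)) {
      edt_out <- distance_transform3(!mask$data, sp_sub) # dist to mask
      near <- miss[trilinear(edt_out, p[miss, , drop = FALSE], sp_sub,
                             outside = Inf) <= max_dist]
      if (length(near)) {
        mpts <- mask_points(mask)
        vals_in <- values[arrayInd(which(mask$data), dim(mask$data))]
        for (j in near) {
          d2 <- colSums((t(mpts) - p[j, ])^2)
          k <- which.min(d2)
          if (sqrt(d2[k]) <= max_dist) out[j] <- vals_in[k]
        }
      }
    }
  } else {
    if (is.null(wall)) stop("wall points required for domain = 'wall'",
                            call. = FALSE)
    stopifnot(length(values) == nrow(wall))
    wp <- apply_affine(T, cbind(wall$x, wall$y, wall$z))
    sw <- cbind(shared$wall$x, shared$wall$y, shared$wall$z)
    out <- rep(NA_real_, nrow(sw))
    for (j in seq_len(nrow(sw))) {
      d2 <- (wp[, 1] - sw[j, 1])^2 + (wp[, 2] - sw[j, 2])^2 +
        (wp[, 3] - sw[j, 3])^2
      k <- which.min(d2)
      if (sqrt(d2[k]) <= max_dist) out[j] <- values[k]
    }
  }
  attr(out, "transform") <- T
  attr(out, "dice") <- fit$dice
  out
}

#' Average mapped subject values per cohort
#'
#' @param maps list of per-subject value vectors from
#'   \code{\link{map_subject}} (one cohort, shared locations aligned).
#' @return object of class \code{cohort_map}: list(values = locations x
#'   subjects matrix, mean = per-location mean over non-missing subjects
#'   (NA where fewer than two contribute), n_subjects = per-location count).
#' @export
cohort_average <- function(maps) {
  values <- do.call(cbind, lapply(maps, as.numeric))
  n_sub <- rowSums(!is.na(values))
  mu <- rowMeans(values, na.rm = TRUE)
  mu[n_sub < 2] <- NA_real_
  structure(list(values = values, mean = mu, n_subjects = n_sub),
            class = "cohort_map")
}

#' @export
print.cohort_map <- function(x, ...) {
  cat(sprintf("<cohort_map> %d locations x %d subjects (%d locations with n >= 2)\n",
              nrow(x$values), ncol(x$values), sum(x$n_subjects >= 2)))
  invisible(x)
}

#' Maximum intensity projection
#'
#' @param volume 3D numeric array.
#' @param axis projection axis (1 = x, 2 = y, 3 = z); the default 2
#'   approximates a sagittal view for the phantom orientation.
#' @return 2D matrix of per-ray maxima.
#' @export
maximum_intensity_projection <- function(volume, axis = 2) {
  stopifnot(length(dim(volume)) == 3)
  apply(volume, setdiff(1:3, axis), max)
}
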