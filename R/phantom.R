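# Analytic 4D-flow phantoms: tubular ascending-aorta-like geometry carrying
# Poiseuille, Womersley or eccentric-jet flow, with closed-form wall shear
# stress and viscous dissipation for the steady parabolic case. The
# corruption stage applies the inverse of the pre-processing corrections
# (eddy-current plane, venc wrapping, Gaussian velocity noise).

BLOOD_DENSITY <- 1060 # kg/m^3, used only for the Womersley number

#' Phantom configuration
#'
#' Defaults mirror a clinical 4D-flow acquisition of the ascending aorta:
#' 2.0 x 1.7 x 2.2 mm^3 voxels, 18 cardiac phases at 40 ms, peak velocities
#' in the 2-2.5 m/s range downstream of a bioprosthetic valve.
#'
#' @param grid_shape integer length 3, voxels per axis.
#' @param spacing voxel spacing in mm.
#' @param n_frames number of cardiac phases.
#' @param frame_dt temporal resolution in ms.
#' @param tube_radius lumen radius R in mm.
#' @param tube_length tube length L in mm.
#' @param centerline "straight" or "arc".
#' @param bend_radius arc bend radius in mm (centerline = "arc").
#' @param profile "poiseuille", "womersley" or "eccentric_jet".
#' @param v_max peak velocity in m/s.
#' @param jet_offset radial displacement of the jet axis in mm
#'   (eccentric_jet); must leave the jet core (radius R/2) inside the lumen.
#' @param temporal_envelope per-frame scale factors in [0, 1] with max 1;
#'   default is a systolic pulse peaking at frame 5 over a 0.05 diastolic
#'   floor.
#' @param venc velocity encoding limit per direction, m/s.
#' @param noise_sigma Gaussian velocity noise sd, m/s.
#' @param wrap_enabled apply venc phase wrapping during corruption.
#' @param eddy_plane_coeffs 3 x 4 matrix; per velocity direction (rows) the
#'   constant (m/s) and linear-in-x,y,z (m/s per mm) eddy-current offsets.
#' @param rigid_jitter optional list(rotation = degrees length 3,
#'   translation = mm length 3) applied to the tube geometry.
#' @param seed integer RNG seed for the corruption stage.
#' @return object of class \code{phantom_config}.
#' @export
phantom_config <- function(grid_shape = c(24, 28, 50),
                           spacing = c(2.0, 1.7, 2.2),
                           n_frames = 18,
                           frame_dt = 40,
                           tube_radius = 10,
                           tube_length = 100,
                           centerline = c("straight", "arc"),
                           bend_radius = 150,
                           profile = c("poiseuille", "womersley", "eccentric_jet"),
                           v_max = 2.25,
                           jet_offset = 0,
                           temporal_envelope = NULL,
                           venc = c(1.5, 1.5, 1.5),
                           noise_sigma = 0.05,
                           wrap_enabled = FALSE,
                           eddy_plane_coeffs = matrix(0, 3, 4),
                           rigid_jitter = NULL,
                           seed = 1L) {
  centerline <- match.arg(centerline)
  profile <- match.arg(profile)
  if (tube_radius <= 0) stop("tube_radius must be positive", call. = FALSE)
  if (tube_length <= 0) stop("tube_length must be positive", call. = FALSE)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (v_max < 0) stop("v_max must be nonnegative", call. = FALSE)
  if (jet_offset < 0 || jet_offset + tube_radius / 2 > tube_radius + 1e-9) {
    stop("jet_offset + jet core radius (R/2) must stay inside the lumen",
         call. = FALSE)
  }
  if (is.null(temporal_envelope)) {
    t <- seq_len(n_frames)
    temporal_envelope <- 0.05 + 0.95 * exp(-0.5 * ((t - 5) / 2)^2)
    temporal_envelope[5] <- 1
  }
  if (length(temporal_envelope) != n_frames ||
      any(temporal_envelope < 0) || any(temporal_envelope > 1) ||
      abs(max(temporal_envelope) - 1) > 1e-12) {
    stop("temporal_envelope must lie in [0, 1] with max = 1", call. = FALSE)
  }
  eddy_plane_coeffs <- matrix(as.numeric(eddy_plane_coeffs), 3, 4)
  structure(
    list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
         n_frames = as.integer(n_frames), frame_dt = frame_dt,
         tube_radius = tube_radius, tube_length = tube_length,
         centerline = centerline, bend_radius = bend_radius,
         profile = profile, v_max = v_max, jet_offset = jet_offset,
         temporal_envelope = temporal_envelope,
         venc = rep(as.numeric(venc), length.out = 3),
         noise_sigma = noise_sigma, wrap_enabled = wrap_enabled,
         eddy_plane_coeffs = eddy_plane_coeffs,
         rigid_jitter = rigid_jitter, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Sampled centerline (positions, unit tangents) at ~1 mm arc-length steps,
# with the optional rigid jitter applied.
phantom_centerline <- function(config) {
  d <- config$grid_shape
  sp <- config$spacing
  L <- config$tube_length
  center <- (d - 1) * sp / 2
  s <- seq(0, L, by = 1)
  if (s[length(s)] < L) s <- c(s, L)
  if (config$centerline == "straight") {
    pos <- cbind(center[1], center[2], center[3] - L / 2 + s)
    tan <- matrix(rep(c(0, 0, 1), each = length(s)), ncol = 3)
  } else {
    Rb <- config$bend_radius
    th <- s / Rb
    # arc in the x-z plane, chord re-centered on the grid
    px <- Rb * (1 - cos(th))
    pz <- Rb * sin(th)
    pos <- cbind(center[1] + px - mean(range(px)),
                 center[2],
                 center[3] + pz - mean(range(pz)))
    tan <- cbind(sin(th), 0, cos(th))
  }
  if (!is.null(config$rigid_jitter)) {
    rot <- euler_matrix(config$rigid_jitter$rotation[1] * pi / 180,
                        config$rigid_jitter$rotation[2] * pi / 180,
                        config$rigid_jitter$rotation[3] * pi / 180)
    pos <- sweep(pos, 2, center) %*% t(rot)
    pos <- sweep(pos, 2, center + config$rigid_jitter$translation, "+")
    tan <- tan %*% t(rot)
  }
  list(pos = pos, tan = tan, s = s)
}

# Womersley velocity profile for one pulsatile harmonic: matrix of
# normalized axial velocity (max |.| = 1) over radial positions x frames.
womersley_profile <- function(r_norm, alpha, n_frames) {
  j0 <- function(z) {
    # complex Bessel J0 via its power series; fine for |z| up to ~25
    acc <- rep(1 + 0i, length(z))
    term <- rep(1 + 0i, length(z))
    z2 <- -(z / 2)^2
    for (k in 1:80) {
      term <- term * z2 / k^2
      acc <- acc + term
    }
    acc
  }
  beta <- complex(modulus = alpha, argument = 3 * pi / 4) # i^{3/2} * alpha
  denom <- j0(beta)
  prof <- 1 - j0(beta * r_norm) / denom
  t <- (seq_len(n_frames) - 1) / n_frames
  w <- outer(prof, exp(2i * pi * t))
  w <- Re(w)
  w / max(abs(w))
}

#' Generate an analytic 4D-flow phantom
#'
#' Builds the clean velocity field and magnitude series for a tubular
#' geometry, together with a ground-truth record. For the Poiseuille
#' profile the truth carries the closed forms: wall shear stress
#' 2 mu v_max / R and viscous energy loss 2 pi mu L v_max^2 at the peak
#' frame.
#'
#' @param config a \code{\link{phantom_config}}.
#' @param mu viscosity used for the analytic truth values (cP or a
#'   \code{\link{viscosity}} object).
#' @return list with elements \code{velocity} (\code{velocity_field}),
#'   \code{magnitude} (\code{magnitude_series}) and \code{truth} (list:
#'   \code{mask}, \code{clean_velocity}, \code{v_max_true},
#'   \code{wall_wss_analytic} in Pa, \code{el_analytic} in mW).
#' @export
generate_phantom <- function(config, mu = viscosity(3.2)) {
  mu <- as_viscosity(mu)
  d <- config$grid_shape
  sp <- config$spacing
  R <- config$tube_radius
  L <- config$tube_length
  cl <- phantom_centerline(config)
  pts <- voxel_centers(d, sp)
  nvox <- nrow(pts)

  # nearest centerline sample per voxel
  best_d2 <- rep(Inf, nvox)
  best_i <- rep(1L, nvox)
  for (i in seq_len(nrow(cl$pos))) {
    d2 <- (pts[, 1] - cl$pos[i, 1])^2 + (pts[, 2] - cl$pos[i, 2])^2 +
      (pts[, 3] - cl$pos[i, 3])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_i[upd] <- i
  }
  tan <- cl$tan[best_i, , drop = FALSE]
  rel <- pts - cl$pos[best_i, , drop = FALSE]
  ax <- rowSums(rel * tan)                       # residual axial offset
  s_global <- cl$s[best_i] + ax
  rad_vec <- rel - tan * ax
  r <- sqrt(rowSums(rad_vec^2))
  inside <- r <= R & s_global >= 0 & s_global <= L
  if (!any(inside)) stop("tube geometry produced an empty mask", call. = FALSE)

  mask_arr <- array(inside, d)
  idx <- arrayInd(which(inside), d)
  touches_edge <- any(idx[, 1] %in% c(1L, d[1])) ||
    any(idx[, 2] %in% c(1L, d[2])) || any(idx[, 3] %in% c(1L, d[3]))
  if (touches_edge) {
    stop("tube is not contained in the grid; enlarge grid_shape or shrink the tube",
         call. = FALSE)
  }

  ins <- which(inside)
  nin <- length(ins)
  # spatial profile factor per inside voxel (frame-independent part)
  if (config$profile == "poiseuille") {
    prof <- config$v_max * pmax(0, 1 - (r[ins] / R)^2)
    prof_t <- outer(prof, config$temporal_envelope)
  } else if (config$profile == "eccentric_jet") {
    e_off <- -tan * tan[, 1]
    e_off[, 1] <- e_off[, 1] + 1 # component of ex orthogonal to the axis
    nrm <- sqrt(rowSums(e_off^2))
    fallback <- nrm < 1e-6
    if (any(fallback)) {
      e_alt <- -tan * tan[, 2]
      e_alt[, 2] <- e_alt[, 2] + 1
      e_off[fallback, ] <- e_alt[fallback, , drop = FALSE]
      nrm[fallback] <- sqrt(rowSums(e_off[fallback, , drop = FALSE]^2))
    }
    e_off <- e_off / nrm
    jet_axis_dist <- sqrt(rowSums((rad_vec - config$jet_offset * e_off)^2))
    core <- R / 2
    prof <- config$v_max * pmax(0, 1 - (jet_axis_dist[ins] / core)^2)
    prof_t <- outer(prof, config$temporal_envelope)
  } else { # womersley
    omega <- 2 * pi / (config$n_frames * config$frame_dt / 1000)
    alpha <- (R / 1000) * sqrt(omega * BLOOD_DENSITY / mu$pa_s)
    w <- womersley_profile(r[ins] / R, alpha, config$n_frames)
    prof_t <- config$v_max * w *
      matrix(config$temporal_envelope, nin, config$n_frames, byrow = TRUE)
  }

  vel <- array(0, c(d, 3, config$n_frames))
  stride <- prod(d)
  for (f in seq_len(config$n_frames)) {
    for (dir in 1:3) {
      off <- stride * (dir - 1) + stride * 3 * (f - 1)
      vel[ins + off] <- prof_t[, f] * tan[ins, dir]
    }
  }

  field <- velocity_field(vel, sp, config$frame_dt, config$venc)
  mag <- array(0.05, c(d, config$n_frames))
  for (f in seq_len(config$n_frames)) {
    mag[cbind(idx, f)] <- 1
  }
  magnitude <- magnitude_series(mag, sp)

  if (config$profile == "poiseuille") {
    wss_true <- if (config$v_max == 0) 0 else 2 * mu$pa_s * config$v_max / (R / 1000)
    el_true <- if (config$v_max == 0) 0 else
      2 * pi * mu$pa_s * (L / 1000) * config$v_max^2 * 1000 # mW
  } else {
    wss_true <- NA_real_
    el_true <- NA_real_
  }
  truth <- list(
    mask = aorta_mask(mask_arr, sp),
    clean_velocity = field,
    v_max_true = config$v_max,
    wall_wss_analytic = wss_true,
    el_analytic = el_true,
    mu_cP = mu$cP
  )
  list(velocity = field, magnitude = magnitude, truth = truth)
}

#' Corrupt a clean phantom velocity field
#'
#' Applies, in acquisition order: per-direction Gaussian velocity noise,
#' a stationary eddy-current offset plane added to every frame, and (if
#' enabled) venc phase wrapping v -> v - 2 venc round(v / (2 venc)).
#' Fully reproducible from \code{config$seed}.
#'
#' @param field clean \code{velocity_field}.
#' @param config the \code{\link{phantom_config}} holding noise_sigma,
#'   eddy_plane_coeffs, venc, wrap_enabled and seed.
#' @return corrupted \code{velocity_field}.
#' @export
corrupt_phantom <- function(field, config) {
  d <- dim(field$data)
  if (config$wrap_enabled && any(config$venc <= 0)) {
    stop("venc must be positive when wrap_enabled", call. = FALSE)
  }
  data <- field$data
  with_seed(config$seed, {
    if (config$noise_sigma > 0) {
      data <- data + array(stats::rnorm(length(data), 0, config$noise_sigma), d)
    }
  })
  if (any(config$eddy_plane_coeffs != 0)) {
    pts <- voxel_centers(d[1:3], field$spacing)
    for (dir in 1:3) {
      cf <- config$eddy_plane_coeffs[dir, ]
      plane <- array(cf[1] + cf[2] * pts[, 1] + cf[3] * pts[, 2] + cf[4] * pts[, 3],
                     d[1:3])
      for (f in seq_len(d[5])) {
        data[, , , dir, f] <- data[, , , dir, f] + plane
      }
    }
  }
  if (config$wrap_enabled) {
    for (dir in 1:3) {
      venc <- config$venc[dir]
      v <- data[, , , dir, , drop = FALSE]
      data[, , , dir, ] <- v - 2 * venc * round(v / (2 * venc))
    }
  }
  velocity_field(data, field$spacing, field$frame_dt, field$venc)
}

#' Generate two synthetic cohorts differing in jet eccentricity
#'
#' Group A ("stented-like") subjects carry an eccentric systolic jet whose
#' offset and peak velocity are drawn around the base setting plus the
#' planted effect; group B ("stentless-like") subjects are drawn around the
#' central setting. Each subject receives a small rigid geometric jitter
#' (rotations up to 5 degrees, translations up to 3 mm) so that atlas
#' registration is exercised, and is corrupted with its own derived seed.
#'
#' @param n_per_group subjects per cohort (>= 2).
#' @param base base \code{\link{phantom_config}}.
#' @param effect list or named vector with \code{jet_offset} (mm) and
#'   \code{v_max} (m/s): group A minus group B differences.
#' @param seed master seed; all per-subject randomness derives from it.
#' @param sd_jet_offset between-subject sd of the jet offset, mm.
#' @param sd_v_max between-subject sd of the peak velocity, m/s.
#' @return list with \code{stented} and \code{stentless}: lists of subjects,
#'   each a list(id, group, config, velocity, magnitude, truth); and
#'   \code{manifest}, a tibble of id and group.
#' @export
generate_cohorts <- function(n_per_group, base = phantom_config(),
                             effect = c(jet_offset = 4, v_max = 0),
                             seed = 1L,
                             sd_jet_offset = 0.3, sd_v_max = 0.05) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  effect <- as.list(effect)
  make_subject <- function(group, i, idx) {
    sseed <- derive_seed(seed, idx)
    pars <- with_seed(sseed, {
      list(
        jet_offset = base$jet_offset +
          (if (group == "stented") effect$jet_offset else 0) +
          stats::rnorm(1, 0, sd_jet_offset),
        v_max = base$v_max +
          (if (group == "stented") effect$v_max else 0) +
          stats::rnorm(1, 0, sd_v_max),
        rotation = stats::runif(3, -5, 5),
        translation = stats::runif(3, -3, 3)
      )
    })
    cfg <- base
    cfg$profile <- "eccentric_jet"
    cfg$jet_offset <- min(max(pars$jet_offset, 0), base$tube_radius / 2)
    cfg$v_max <- max(pars$v_max, 0.1)
    cfg$rigid_jitter <- list(rotation = pars$rotation,
                             translation = pars$translation)
    cfg$seed <- derive_seed(sseed, 1L)
    ph <- generate_phantom(cfg)
    list(id = sprintf("%s_%02d", group, i), group = group, config = cfg,
         velocity = corrupt_phantom(ph$velocity, cfg),
         magnitude = ph$magnitude, truth = ph$truth)
  }
  stented <- lapply(seq_len(n_per_group),
                    function(i) make_subject("stented", i, i))
  stentless <- lapply(seq_len(n_per_group),
                      function(i) make_subject("stentless", i, n_per_group + i))
  manifest <- tibble::tibble(
    id = c(vapply(stented, `[[`, "", "id"),
           vapply(stentless, `[[`, "", "id")),
    group = rep(c("stented", "stentless"), each = n_per_group)
  )
  list(stented = stented, stentless = stentless, manifest = manifest)
}
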