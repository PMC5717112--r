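# S3 containers for 4D-flow data. Velocity fields and masks are arrays with
# geometry metadata; everything naturally tabular (wall points, WSS maps,
# summaries) is a tibble.

#' Construct a time-resolved three-directional velocity field
#'
#' The central container of the pipeline: a 5D array of velocities in m/s
#' indexed \code{[x, y, z, direction, frame]}, together with the voxel
#' spacing, frame timing and per-direction velocity-encoding limit (venc).
#'
#' @param data numeric array, dim \code{c(nx, ny, nz, 3, n_frames)}, m/s.
#' @param spacing numeric length 3, voxel spacing in mm.
#' @param frame_dt temporal resolution in ms.
#' @param venc velocity encoding limit per direction, m/s (recycled to 3).
#' @return object of class \code{velocity_field}.
#' @export
velocity_field <- function(data, spacing, frame_dt, venc) {
  stopifnot(length(dim(data)) == 5, dim(data)[4] == 3)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (dim(data)[5] < 1) stop("at least one frame required", call. = FALSE)
  if (!all(is.finite(data))) stop("velocity data must be finite", call. = FALSE)
  venc <- rep(venc, length.out = 3)
  structure(
    list(data = data, spacing = as.numeric(spacing),
         frame_dt = as.numeric(frame_dt), venc = as.numeric(venc)),
    class = "velocity_field"
  )
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<velocity_field> %d x %d x %d voxels, %d frames @ %.0f ms, spacing %s mm, venc %s m/s\n",
    d[1], d[2], d[3], d[5], x$frame_dt,
    paste(format(x$spacing, digits = 3), collapse = " x "),
    paste(format(x$venc, digits = 3), collapse = "/")
  ))
  invisible(x)
}

#' @export
dim.velocity_field <- function(x) dim(x$data)

n_frames <- function(field) dim(field$data)[5]

# Single time frame as an array [x, y, z, direction].
get_frame <- function(field, frame) {
  field$data[, , , , frame, drop = TRUE]
}

# Voxelwise speed |v| of one frame array [x, y, z, 3].
speed_volume <- function(frame_arr) {
  sqrt(frame_arr[, , , 1]^2 + frame_arr[, , , 2]^2 + frame_arr[, , , 3]^2)
}

#' Construct a magnitude image series
#'
#' @param data numeric array \code{c(nx, ny, nz, n_frames)}, arbitrary units.
#' @param spacing voxel spacing in mm.
#' @return object of class \code{magnitude_series}.
#' @export
magnitude_series <- function(data, spacing) {
  stopifnot(length(dim(data)) == 4)
  if (any(data < 0)) stop("magnitude must be nonnegative", call. = FALSE)
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "magnitude_series")
}

#' @export
print.magnitude_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<magnitude_series> %d x %d x %d voxels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Construct a PC-MRA volume
#'
#' Angiogram-like contrast volume: magnitude times velocity magnitude,
#' averaged over the cardiac cycle.
#'
#' @param data nonnegative 3D array.
#' @param spacing voxel spacing in mm.
#' @return object of class \code{pcmra_volume}.
#' @export
pcmra_volume <- function(data, spacing) {
  stopifnot(length(dim(data)) == 3)
  if (any(data < 0)) stop("PC-MRA must be nonnegative", call. = FALSE)
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "pcmra_volume")
}

#' Construct an aortic lumen mask
#'
#' @param data logical 3D array (TRUE inside the lumen).
#' @param spacing voxel spacing in mm.
#' @param check require a nonempty single connected component.
#' @return object of class \code{aorta_mask} with \code{voxel_volume} in mm^3.
#' @export
aorta_mask <- function(data, spacing, check = TRUE) {
  stopifnot(length(dim(data)) == 3)
  data <- array(as.logical(data), dim(data))
  if (check && !any(data)) stop("mask is empty", call. = FALSE)
  structure(
    list(data = data, spacing = as.numeric(spacing),
         voxel_volume = prod(spacing)),
    class = "aorta_mask"
  )
}

#' @export
print.aorta_mask <- function(x, ...) {
  cat(sprintf("<aorta_mask> %d voxels (%.1f ml), spacing %s mm\n",
              sum(x$data), sum(x$data) * x$voxel_volume / 1000,
              paste(format(x$spacing, digits = 3), collapse = " x ")))
  invisible(x)
}

#' Dynamic viscosity
#'
#' Stored internally in Pa.s; constructed from centipoise as used in the
#' haemodynamics literature. Whole blood at the assumed haematocrit is
#' conventionally 3.2 cP.
#'
#' @param cP dynamic viscosity in centipoise.
#' @return object of class \code{viscosity}.
#' @export
viscosity <- function(cP = 3.2) {
  if (cP <= 0) stop("viscosity must be positive", call. = FALSE)
  structure(list(cP = cP, pa_s = cP * 1e-3), class = "viscosity")
}

as_viscosity <- function(mu) {
  if (inherits(mu, "viscosity")) mu else viscosity(mu)
}

#' @export
print.viscosity <- function(x, ...) {
  cat(sprintf("<viscosity> %.2f cP (%.2e Pa.s)\n", x$cP, x$pa_s))
  invisible(x)
}
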