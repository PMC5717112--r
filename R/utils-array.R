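# Low-level 3D array utilities shared across the pipeline.
# Volumes are dense arrays with dim c(nx, ny, nz); voxel centers sit at
# (i - 1) * spacing along each axis so index 1 maps to physical 0 mm.

#' Voxel center coordinates of a grid
#'
#' @param dim integer length-3 grid shape.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return matrix with one row per voxel (column-major order) and columns
#'   x, y, z in mm.
#' @keywords internal
voxel_centers <- function(dim, spacing) {
  idx <- arrayInd(seq_len(prod(dim)), dim)
  cbind(
    x = (idx[, 1] - 1) * spacing[1],
    y = (idx[, 2] - 1) * spacing[2],
    z = (idx[, 3] - 1) * spacing[3]
  )
}

# Shift a 3D array by integer offsets, padding with `fill`.
shift3 <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (length(sx) < 1 || length(sy) < 1 || length(sz) < 1) return(out)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

# Offsets of the 26-neighborhood (excluding center).
neighbor_offsets <- function(connectivity = 26) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  as.matrix(g)
}

#' 3x3x3 median filter with reflected edge padding
#'
#' @param vol 3D numeric array.
#' @return filtered array of the same shape.
#' @keywords internal
median_filter3 <- function(vol) {
  d <- dim(vol)
  array(.median_filter3_cpp(as.numeric(vol), as.integer(d)), d)
}

# Separable Gaussian smoothing, sigma in voxels per axis, replicate padding.
gauss_smooth3 <- function(vol, sigma = 1) {
  sigma <- rep(sigma, length.out = 3)
  out <- vol
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-0.5 * ((-r:r) / s)^2)
    w <- w / sum(w)
    d <- dim(out)
    acc <- array(0, d)
    for (k in -r:r) {
      sh <- c(0L, 0L, 0L)
      sh[ax] <- k
      # replicate padding: clamp source indices
      idx <- pmin(pmax(seq_len(d[ax]) - sh[ax], 1L), d[ax])
      sl <- switch(ax,
        out[idx, , , drop = FALSE],
        out[, idx, , drop = FALSE],
        out[, , idx, drop = FALSE]
      )
      acc <- acc + w[k + r + 1] * sl
    }
    out <- acc
  }
  out
}

# Binary dilation/erosion with a 3x3x3 box (26-connectivity + center).
dilate3 <- function(mask) {
  off <- neighbor_offsets(26)
  out <- mask
  for (i in seq_len(nrow(off))) {
    out <- out | shift3(mask, off[i, 1], off[i, 2], off[i, 3], fill = FALSE)
  }
  out
}

erode3 <- function(mask) {
  off <- neighbor_offsets(26)
  out <- mask
  for (i in seq_len(nrow(off))) {
    out <- out & shift3(mask, off[i, 1], off[i, 2], off[i, 3], fill = FALSE)
  }
  out
}

# Morphological closing (dilate then erode), one pass.
close3 <- function(mask) erode3(dilate3(mask))

#' Label connected components of a binary volume
#'
#' Breadth-first flood fill; frontier expansion is vectorized over the 26
#' (or 6) neighbor shifts, so cost scales with component diameter.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return integer array of labels, 0 outside.
#' @keywords internal
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  labels <- array(0L, d)
  off <- neighbor_offsets(connectivity)
  unvisited <- mask
  lab <- 0L
  while (any(unvisited)) {
    lab <- lab + 1L
    seed <- which(unvisited)[1]
    comp <- array(FALSE, d)
    comp[seed] <- TRUE
    frontier <- comp
    repeat {
      grown <- frontier
      for (i in seq_len(nrow(off))) {
        grown <- grown | shift3(frontier, off[i, 1], off[i, 2], off[i, 3], fill = FALSE)
      }
      grown <- grown & unvisited & !comp
      if (!any(grown)) break
      comp <- comp | grown
      frontier <- grown
    }
    labels[comp] <- lab
    unvisited <- unvisited & !comp
  }
  labels
}

# Keep the largest connected component of a binary volume.
largest_component <- function(mask, connectivity = 26) {
  labels <- label_components(mask, connectivity)
  if (max(labels) == 0L) return(mask & FALSE)
  sizes <- tabulate(labels[labels > 0L])
  labels == which.max(sizes)
}

#' Anisotropic Euclidean distance transform
#'
#' Distance (mm) from every voxel center to the nearest voxel center
#' outside the mask, by the lower-envelope (parabola) algorithm applied
#' separably along the three axes.
#'
#' @param mask logical 3D array.
#' @param spacing numeric length-3, mm.
#' @return numeric array of distances in mm (0 outside the mask).
#' @keywords internal
distance_transform3 <- function(mask, spacing) {
  d <- dim(mask)
  # large finite sentinel keeps the lower-envelope arithmetic well defined
  f <- array(ifelse(mask, 1e15, 0), d)
  for (ax in 1:3) {
    s <- spacing[ax]
    n <- d[ax]
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    fp <- aperm(f, perm)
    dp <- dim(fp)
    m <- matrix(fp, nrow = dp[1])
    for (col in seq_len(ncol(m))) {
      m[, col] <- dt1d(m[, col], s)
    }
    fp <- array(m, dp)
    f <- aperm(fp, order(perm))
  }
  sqrt(f)
}

# 1D squared-distance transform over samples at positions i*s (Felzenszwalb
# & Huttenlocher lower envelope). Inputs must be finite.
dt1d <- function(f, s) {
  n <- length(f)
  if (n == 1 || all(f == 0)) return(f)
  v <- integer(n)   # parabola sites
  z <- numeric(n + 1) # envelope breakpoints
  k <- 1L
  v[1] <- 1L
  z[1] <- -Inf
  z[2] <- Inf
  for (q in 2:n) {
    repeat {
      p <- v[k]
      sden <- 2 * s * s * (q - p)
      sval <- ((f[q] + (q * s)^2) - (f[p] + (p * s)^2)) / sden
      if (k > 1L && sval <= z[k]) {
        k <- k - 1L
      } else {
        break
      }
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- sval
    z[k + 1] <- Inf
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    # breakpoints are kept in index units
    while (z[k + 1] < q) k <- k + 1L
    p <- v[k]
    out[q] <- ((q - p) * s)^2 + f[p]
  }
  out
}

#' Trilinear interpolation of a 3D volume at physical points
#'
#' @param vol 3D numeric array.
#' @param pts n x 3 matrix of positions in mm.
#' @param spacing voxel spacing, mm.
#' @param outside value returned for points outside the grid.
#' @return numeric vector of length n.
#' @keywords internal
trilinear <- function(vol, pts, spacing, outside = 0) {
  d <- dim(vol)
  gx <- pts[, 1] / spacing[1] + 1
  gy <- pts[, 2] / spacing[2] + 1
  gz <- pts[, 3] / spacing[3] + 1
  ok <- gx >= 1 & gx <= d[1] & gy >= 1 & gy <= d[2] & gz >= 1 & gz <= d[3]
  out <- rep(outside, nrow(pts))
  if (!any(ok)) return(out)
  gx <- gx[ok]; gy <- gy[ok]; gz <- gz[ok]
  i0 <- pmin(floor(gx), d[1] - 1); j0 <- pmin(floor(gy), d[2] - 1)
  k0 <- pmin(floor(gz), d[3] - 1)
  if (d[1] == 1) i0 <- rep(1, length(gx))
  if (d[2] == 1) j0 <- rep(1, length(gy))
  if (d[3] == 1) k0 <- rep(1, length(gz))
  wx <- gx - i0; wy <- gy - j0; wz <- gz - k0
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  val <-
    vol[cbind(i0, j0, k0)] * (1 - wx) * (1 - wy) * (1 - wz) +
    vol[cbind(i1, j0, k0)] * wx * (1 - wy) * (1 - wz) +
    vol[cbind(i0, j1, k0)] * (1 - wx) * wy * (1 - wz) +
    vol[cbind(i0, j0, k1)] * (1 - wx) * (1 - wy) * wz +
    vol[cbind(i1, j1, k0)] * wx * wy * (1 - wz) +
    vol[cbind(i1, j0, k1)] * wx * (1 - wy) * wz +
    vol[cbind(i0, j1, k1)] * (1 - wx) * wy * wz +
    vol[cbind(i1, j1, k1)] * wx * wy * wz
  out[ok] <- val
  out
}

# Rotation matrix from intrinsic x-y-z Euler angles (radians): Rz %*% Ry %*% Rx.
euler_matrix <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a per-subject seed from a master seed, staying inside 32-bit range.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 2654435761 + i * 97561) %% 2147483647)
}
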