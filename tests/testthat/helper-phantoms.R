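# Shared fixtures and independent oracles. Phantoms are generated in code
# and cached per session so repeated tests stay fast.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default-grid unit Poiseuille phantom (the main analytic oracle).
poiseuille_default <- function() {
  cached("poiseuille_default", {
    generate_phantom(phantom_config(v_max = 1, noise_sigma = 0))
  })
}

# Small, fast tube phantom for structural tests.
small_tube <- function(v_max = 1, ...) {
  generate_phantom(phantom_config(
    grid_shape = c(16, 16, 18), spacing = c(2, 2, 2),
    tube_radius = 6, tube_length = 28, v_max = v_max,
    noise_sigma = 0, ...))
}

# Single-frame velocity array; the default envelope peaks at frame 5.
peak_frame_arr <- function(ph, frame = 5) {
  fr <- ph$velocity$data[, , , , frame]
  dim(fr) <- dim(ph$velocity$data)[1:4]
  fr
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Independent Mann-Whitney oracle: full enumeration of the null
# permutation distribution of the rank-sum statistic.
mwu_enumerate <- function(x, y) {
  m <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mid <- m * length(y) / 2
  combos <- utils::combn(length(pool), m)
  us <- apply(combos, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  mean(abs(us - mid) >= abs(U_obs - mid) - 1e-12)
}

# Analytic closed forms for the steady parabolic profile.
wss_poiseuille <- function(mu_pa_s, v_max, R_mm) 2 * mu_pa_s * v_max / (R_mm / 1000)
el_poiseuille_mw <- function(mu_pa_s, L_mm, v_max) {
  2 * pi * mu_pa_s * (L_mm / 1000) * v_max^2 * 1000
}

# Wrap a plain matrix (locations x subjects) as a cohort_map.
make_cohort_map <- function(mat) {
  structure(list(values = mat, mean = rowMeans(mat, na.rm = TRUE),
                 n_subjects = rowSums(!is.na(mat))), class = "cohort_map")
}

# Reference/moving phantom pair with a known rigid jitter.
make_jittered_pair <- function() {
  cached("atlas_pair", {
    base <- phantom_config(grid_shape = c(20, 22, 40), spacing = c(2, 2, 2),
                           tube_radius = 8, tube_length = 68,
                           v_max = 1, noise_sigma = 0)
    jit <- base
    jit$rigid_jitter <- list(rotation = c(3, -4, 2),
                             translation = c(2, -1.5, 2.5))
    list(base = base, ref = generate_phantom(base), mov = generate_phantom(jit))
  })
}

# WSS of the default Poiseuille phantom evaluated in a rotated frame, at
# wall points carried over (rotated) from the unrotated extraction, so the
# comparison is per matched point.
rotated_wss <- function(wall, rotation_deg) {
  cfg <- phantom_config(v_max = 1, noise_sigma = 0,
                        rigid_jitter = list(rotation = rotation_deg,
                                            translation = c(0, 0, 0)))
  ph <- generate_phantom(cfg)
  Rm <- aortaflow:::euler_matrix(rotation_deg[1] * pi / 180,
                                 rotation_deg[2] * pi / 180,
                                 rotation_deg[3] * pi / 180)
  ctr <- (cfg$grid_shape - 1) * cfg$spacing / 2
  p <- cbind(wall$x, wall$y, wall$z)
  n <- cbind(wall$nx, wall$ny, wall$nz)
  p2 <- sweep(sweep(p, 2, ctr) %*% t(Rm), 2, ctr, "+")
  n2 <- n %*% t(Rm)
  w2 <- wall
  w2$x <- p2[, 1]; w2$y <- p2[, 2]; w2$z <- p2[, 3]
  w2$nx <- n2[, 1]; w2$ny <- n2[, 2]; w2$nz <- n2[, 3]
  compute_wss(peak_frame_arr(ph), w2, viscosity(3.2), mask = ph$truth$mask)
}
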