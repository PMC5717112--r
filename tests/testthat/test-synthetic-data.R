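# Phantom generator: analytic truth, corruption model, cohort draws.

test_that("poiseuille truth carries the closed-form WSS and EL", {
  ph <- generate_phantom(phantom_config(v_max = 1, noise_sigma = 0),
                         mu = viscosity(3.2))
  expect_equal(ph$truth$wall_wss_analytic, 0.64, tolerance = 1e-12)
  expect_equal(ph$truth$el_analytic, 2 * pi * 3.2e-3 * 0.1 * 1000 * 1,
               tolerance = 1e-12)
  expect_equal(ph$truth$v_max_true, 1)
})

test_that("null flow phantom has zero velocity and zero truth", {
  ph <- small_tube(v_max = 0)
  expect_true(all(ph$velocity$data == 0))
  expect_equal(ph$truth$wall_wss_analytic, 0)
  expect_equal(ph$truth$el_analytic, 0)
  expect_gt(sum(ph$truth$mask$data), 0)
})

test_that("phantom mask matches the analytic cylinder within one voxel", {
  ph <- poiseuille_default()
  m <- ph$truth$mask
  d <- dim(m$data); sp <- m$spacing
  ctr <- (d - 1) * sp / 2
  pts <- aortaflow:::voxel_centers(d, sp)
  r <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  s <- pts[, 3] - (ctr[3] - 50)
  analytic <- r <= 10 & s >= 0 & s <= 100
  # disagreement allowed only within one voxel of the analytic surface
  margin <- max(sp)
  near_surface <- abs(r - 10) <= margin | abs(s) <= margin | abs(s - 100) <= margin
  expect_true(all(m$data[which(analytic & !near_surface)]))
  expect_true(!any(m$data[which(!analytic & !near_surface)]))
})

test_that("velocity follows the parabolic profile scaled by the envelope", {
  ph <- small_tube()
  cfg <- phantom_config(grid_shape = c(16, 16, 22), spacing = c(2, 2, 2),
                        tube_radius = 6, tube_length = 28, v_max = 1,
                        noise_sigma = 0)
  d <- dim(ph$velocity$data)
  ctr <- (d[1:3] - 1) * c(2, 2, 2) / 2
  pts <- aortaflow:::voxel_centers(d[1:3], c(2, 2, 2))
  r <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  inside <- ph$truth$mask$data
  vz5 <- ph$velocity$data[, , , 3, 5]
  expect_equal(vz5[inside], (1 - (r[inside] / 6)^2) * cfg$temporal_envelope[5],
               tolerance = 1e-10)
  # another frame scales by its envelope factor
  vz9 <- ph$velocity$data[, , , 3, 9]
  expect_equal(vz9[inside], vz5[inside] / cfg$temporal_envelope[5] *
                 cfg$temporal_envelope[9], tolerance = 1e-10)
  # zero outside, x/y components zero for the straight tube
  expect_true(all(vz5[!inside] == 0))
  expect_true(all(ph$velocity$data[, , , 1:2, ] == 0))
})

test_that("oversized tubes raise a geometry error", {
  expect_error(generate_phantom(phantom_config(tube_radius = 30)),
               "not contained")
  expect_error(phantom_config(jet_offset = 8, tube_radius = 10),
               "jet core")
})

test_that("identity corruption returns the input bit-for-bit", {
  cfg <- phantom_config(grid_shape = c(16, 16, 22), spacing = c(2, 2, 2),
                        tube_radius = 6, tube_length = 28,
                        noise_sigma = 0, wrap_enabled = FALSE)
  ph <- generate_phantom(cfg)
  out <- corrupt_phantom(ph$velocity, cfg)
  expect_identical(out$data, ph$velocity$data)
})

test_that("wrap arithmetic maps +1.60 to -1.40 at venc 1.50", {
  cfg <- phantom_config(grid_shape = c(5, 5, 5), spacing = c(2, 2, 2),
                        tube_radius = 2, tube_length = 4, noise_sigma = 0,
                        wrap_enabled = TRUE, venc = 1.5)
  arr <- array(0, c(5, 5, 5, 3, 2))
  arr[2, 2, 2, 1, 1] <- 1.60
  field <- velocity_field(arr, c(2, 2, 2), 40, 1.5)
  out <- corrupt_phantom(field, cfg)
  expect_equal(out$data[2, 2, 2, 1, 1], -1.40, tolerance = 1e-12)
  expect_error(
    corrupt_phantom(field, phantom_config(wrap_enabled = TRUE, venc = 0)),
    "venc")
})

test_that("corruption is reproducible from the seed", {
  cfg <- phantom_config(grid_shape = c(16, 16, 22), spacing = c(2, 2, 2),
                        tube_radius = 6, tube_length = 28,
                        noise_sigma = 0.05, seed = 42)
  ph <- generate_phantom(cfg)
  a <- corrupt_phantom(ph$velocity, cfg)
  b <- corrupt_phantom(ph$velocity, cfg)
  expect_identical(a$data, b$data)
})

test_that("cohort generation is seeded and balanced", {
  base <- phantom_config(grid_shape = c(16, 16, 22), spacing = c(2, 2, 2),
                         tube_radius = 6, tube_length = 28)
  c1 <- generate_cohorts(2, base, effect = c(jet_offset = 2, v_max = 0),
                         seed = 5)
  c2 <- generate_cohorts(2, base, effect = c(jet_offset = 2, v_max = 0),
                         seed = 5)
  expect_identical(c1$stented[[1]]$velocity$data, c2$stented[[1]]$velocity$data)
  expect_identical(c1$manifest, c2$manifest)
  expect_equal(nrow(c1$manifest), 4)
  expect_error(generate_cohorts(1, base), "n_per_group")
  # planted effect shifts group A's jet offset
  offs <- function(coh, g) vapply(coh[[g]], function(s) s$config$jet_offset, 0)
  expect_gt(mean(offs(c1, "stented")), mean(offs(c1, "stentless")) + 1)
})

test_that("null effect draws both cohorts from one distribution", {
  base <- phantom_config(grid_shape = c(16, 16, 22), spacing = c(2, 2, 2),
                         tube_radius = 6, tube_length = 28)
  coh <- generate_cohorts(6, base, effect = c(jet_offset = 0, v_max = 0),
                          seed = 9)
  offs <- c(vapply(coh$stented, function(s) s$config$jet_offset, 0),
            vapply(coh$stentless, function(s) s$config$jet_offset, 0))
  vmax <- c(vapply(coh$stented, function(s) s$config$v_max, 0),
            vapply(coh$stentless, function(s) s$config$v_max, 0))
  # same construction rule for both groups: a location-scale family around
  # the base values, so group means differ only by sampling noise
  expect_lt(abs(mean(offs[1:6]) - mean(offs[7:12])), 0.5)
  expect_lt(abs(mean(vmax[1:6]) - mean(vmax[7:12])), 0.1)
})

test_that("womersley profile vanishes at the wall and stays bounded", {
  cfg <- phantom_config(grid_shape = c(16, 16, 22), spacing = c(2, 2, 2),
                        tube_radius = 6, tube_length = 28,
                        profile = "womersley", v_max = 1, noise_sigma = 0)
  ph <- generate_phantom(cfg)
  expect_lte(max(abs(ph$velocity$data)), 1 + 1e-9)
  expect_true(is.na(ph$truth$wall_wss_analytic))
  # speed at the outermost mask ring is far below the core speed
  sp5 <- speed <- sqrt(ph$velocity$data[, , , 1, 5]^2 +
                         ph$velocity$data[, , , 2, 5]^2 +
                         ph$velocity$data[, , , 3, 5]^2)
  d <- dim(sp5); ctr <- (d - 1) * 2 / 2
  pts <- aortaflow:::voxel_centers(d, c(2, 2, 2))
  r <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  ring <- ph$truth$mask$data & array(r > 5, d)
  core <- ph$truth$mask$data & array(r < 2, d)
  expect_lt(mean(sp5[ring]), mean(sp5[core]))
})
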