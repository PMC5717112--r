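# Peak-systole selection, median filtering, velocity metrics, WSS, EL.

test_that("peak systole is the frame with maximal mean speed, earliest on ties", {
  ph <- small_tube()
  expect_equal(find_peak_systole(ph$velocity, ph$truth$mask), 5)

  # constant-in-time field: first frame wins the tie
  f <- ph$velocity
  for (fr in seq_len(dim(f$data)[5])) f$data[, , , , fr] <- f$data[, , , , 5]
  expect_equal(find_peak_systole(f, ph$truth$mask), 1)

  # single-frame field
  arr <- f$data[, , , , 1, drop = FALSE]
  f1 <- velocity_field(array(arr, c(dim(f$data)[1:4], 1)), f$spacing,
                       f$frame_dt, f$venc)
  expect_equal(find_peak_systole(f1, ph$truth$mask), 1)
})

test_that("median filter removes spikes, keeps constants and linear ramps", {
  arr <- array(1, c(9, 9, 9, 3))
  arr[5, 5, 5, 1] <- 10
  out <- median_filter_peak(arr)
  expect_equal(out[5, 5, 5, 1], 1)

  const <- array(0.7, c(6, 6, 6, 3))
  expect_equal(median_filter_peak(const), const)

  # linear ramp: interior unchanged (median of a symmetric window of a
  # linear function is its center); verified against a brute-force window
  ramp <- array(0, c(8, 8, 8, 3))
  for (i in 1:8) ramp[i, , , 1] <- 0.3 * i
  out <- median_filter_peak(ramp)
  expect_equal(out[2:7, 2:7, 2:7, 1], ramp[2:7, 2:7, 2:7, 1])
  brute <- median(as.vector(ramp[3:5, 3:5, 3:5, 1]))
  expect_equal(out[4, 4, 4, 1], brute)
})

test_that("peak and mean velocity match the analytic parabolic profile", {
  ph <- poiseuille_default()
  fr <- peak_frame_arr(ph)
  mask <- ph$truth$mask
  pk <- peak_velocity(fr, mask)
  expect_equal(as.numeric(pk), 1, tolerance = 0.05)
  expect_equal(mean_velocity(fr, mask), 0.5, tolerance = 0.05)

  # max is monotone under ROI shrinkage: excluding the core lowers it
  d <- dim(mask$data)
  roi <- mask$data
  pos <- attr(pk, "position")
  roi[max(1, pos[1] - 2):min(d[1], pos[1] + 2),
      max(1, pos[2] - 2):min(d[2], pos[2] + 2), ] <- FALSE
  expect_lt(as.numeric(peak_velocity(fr, mask, roi)), as.numeric(pk))
  expect_error(peak_velocity(fr, mask, array(FALSE, d)), "empty")

  zero <- fr * 0
  expect_equal(as.numeric(peak_velocity(zero, mask)), 0)
  expect_equal(mean_velocity(zero, mask), 0)

  const <- fr * 0; const[, , , 2] <- 0.6
  expect_equal(mean_velocity(const, mask), 0.6, tolerance = 1e-12)
})

test_that("WSS on the Poiseuille phantom matches 2 mu v_max / R", {
  ph <- poiseuille_default()
  fr <- peak_frame_arr(ph)
  wall <- cached("wall_default", extract_wall(ph$truth$mask))
  wss <- compute_wss(fr, wall, viscosity(3.2), mask = ph$truth$mask)
  expect_equal(attr(wss, "mean_wss"), 0.64, tolerance = 0.10)
  # zero field gives zero WSS
  wss0 <- compute_wss(fr * 0, wall, viscosity(3.2), mask = ph$truth$mask)
  expect_equal(max(wss0$wss_mag), 0)
  # WSS vectors are tangential
  ndot <- wss$wssx * wss$nx + wss$wssy * wss$ny + wss$wssz * wss$nz
  expect_lt(max(abs(ndot)), 1e-9)
})

test_that("WSS magnitude is invariant under rigid rotation of the frame", {
  # frame-invariance oracle: rotate the phantom, its analytic field and the
  # matched wall points together; per matched point |WSS| must not change
  ph1 <- poiseuille_default()
  wall1 <- cached("wall_default", extract_wall(ph1$truth$mask))
  w1 <- compute_wss(peak_frame_arr(ph1), wall1, viscosity(3.2),
                    mask = ph1$truth$mask)
  rw <- rotated_wss(wall1, c(4, -3, 0))
  both <- !w1$excluded & !rw$excluded
  expect_lt(abs(mean(rw$wss_mag[both]) / mean(w1$wss_mag[both]) - 1), 0.02)
  expect_lt(stats::median(abs(rw$wss_mag[both] / w1$wss_mag[both] - 1)), 0.02)
})

test_that("energy loss matches 2 pi mu L v_max^2 and refines monotonically", {
  errs <- c()
  for (sc in c(2, 1, 0.5)) {
    cfg <- phantom_config(grid_shape = round(c(24, 28, 50) / sc) + c(0, 0, 2),
                          spacing = c(2.0, 1.7, 2.2) * sc,
                          v_max = 1, noise_sigma = 0)
    ph <- generate_phantom(cfg)
    el <- compute_energy_loss(peak_frame_arr(ph), ph$truth$mask, viscosity(3.2))
    errs <- c(errs, abs(el$total_el / el_poiseuille_mw(3.2e-3, 100, 1) - 1))
  }
  expect_lt(errs[2], 0.10)      # default grid within 10%
  expect_true(all(diff(errs) < 0)) # monotone decrease under refinement
})

test_that("uniform plug flow dissipates nothing in the interior", {
  m <- array(FALSE, c(12, 12, 12)); m[3:10, 3:10, 3:10] <- TRUE
  mask <- aorta_mask(m, c(2, 2, 2))
  fr <- array(0, c(12, 12, 12, 3)); fr[, , , 3] <- 0.8
  el <- compute_energy_loss(fr, mask, viscosity(3.2))
  expect_equal(el$total_el, 0, tolerance = 1e-12)
  # and the zero field too
  expect_equal(compute_energy_loss(fr * 0, mask, viscosity(3.2))$total_el, 0)
})

test_that("WSS and EL scale linearly in viscosity; EL ignores uniform offsets", {
  ph <- small_tube()
  fr <- peak_frame_arr(ph)
  mask <- ph$truth$mask
  wall <- extract_wall(mask)
  w1 <- compute_wss(fr, wall, viscosity(3.2), mask = mask)
  w2 <- compute_wss(fr, wall, viscosity(6.4), mask = mask)
  expect_equal(attr(w2, "mean_wss"), 2 * attr(w1, "mean_wss"),
               tolerance = 1e-12)
  e1 <- compute_energy_loss(fr, mask, viscosity(3.2))
  e2 <- compute_energy_loss(fr, mask, viscosity(6.4))
  expect_equal(e2$total_el, 2 * e1$total_el, tolerance = 1e-12)

  shifted <- fr
  shifted[, , , 1] <- shifted[, , , 1] + 0.37
  shifted[, , , 3] <- shifted[, , , 3] - 0.21
  e3 <- compute_energy_loss(shifted, mask, viscosity(3.2))
  expect_equal(e3$total_el, e1$total_el, tolerance = 1e-9)
})

test_that("summary combines the four metrics with the peak frame", {
  ph <- poiseuille_default()
  summ <- cached("summary_default",
                 summarize_hemodynamics(ph$velocity, ph$truth$mask,
                                        wall = cached("wall_default",
                                                      extract_wall(ph$truth$mask))))
  expect_equal(summ$peak_frame, 5)
  # the 3x3x3 median filter trims the parabolic peak by several percent at
  # this resolution, so the summary tolerances sit above the raw-metric ones
  expect_equal(summ$peak_velocity, 1, tolerance = 0.10)
  expect_equal(summ$mean_velocity, 0.5, tolerance = 0.08)
  expect_equal(summ$mean_wss, 0.64, tolerance = 0.10)
  expect_equal(summ$energy_loss, 2.01, tolerance = 0.15)
  expect_equal(summ$mu_cP, 3.2)
  expect_gte(summ$peak_velocity, summ$mean_velocity)
})

test_that("null flow yields an all-zero summary", {
  ph <- small_tube(v_max = 0)
  summ <- summarize_hemodynamics(ph$velocity, ph$truth$mask)
  expect_equal(summ$peak_velocity, 0)
  expect_equal(summ$mean_velocity, 0)
  expect_equal(summ$mean_wss, 0)
  expect_equal(summ$energy_loss, 0)
  expect_equal(summ$peak_frame, 1)
})

test_that("peak velocity never falls below mean velocity across phantoms", {
  for (vm in c(0.3, 1, 2.2)) {
    ph <- small_tube(v_max = vm)
    summ <- summarize_hemodynamics(ph$velocity, ph$truth$mask)
    expect_gte(summ$peak_velocity, summ$mean_velocity)
  }
})
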