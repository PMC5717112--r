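# Shared geometry, registration, subject mapping, cohort averaging, MIP.

test_that("rigid registration recovers a known jitter", {
  pair <- make_jittered_pair()
  fit <- register_masks(pair$mov$truth$mask, pair$ref$truth$mask, "rigid")
  expect_gt(fit$dice, 0.9)
  d <- pair$base$grid_shape; sp <- pair$base$spacing
  ctr <- (d - 1) * sp / 2
  Rm <- aortaflow:::euler_matrix(3 * pi / 180, -4 * pi / 180, 2 * pi / 180)
  Tinj <- diag(4)
  Tinj[1:3, 1:3] <- Rm
  Tinj[1:3, 4] <- ctr - Rm %*% ctr + c(2, -1.5, 2.5)
  Trec <- fit$transform %*% Tinj # residual, ideally identity
  # tube-axis tilt is the identifiable rotation component (axial spin is a
  # gauge freedom of a rotationally symmetric mask): within 2 degrees
  ez <- Trec[1:3, 1:3] %*% c(0, 0, 1)
  tilt <- acos(min(1, ez[3])) * 180 / pi
  expect_lt(tilt, 2)
  # mean surface displacement under the residual: within one voxel
  pts <- aortaflow:::mask_points(pair$ref$truth$mask)
  disp <- aortaflow:::apply_affine(Trec, pts) - pts
  expect_lt(mean(sqrt(rowSums(disp^2))), max(sp))
})

test_that("identity cohorts give the common mask and identity transforms", {
  ph <- small_tube()
  masks <- list(ph$truth$mask, ph$truth$mask, ph$truth$mask)
  shared <- build_shared_geometry(masks, 0.6)
  expect_equal(array(shared$mask$data, dim(shared$mask$data)),
               ph$truth$mask$data)
  for (T in shared$transforms) {
    pts <- aortaflow:::mask_points(ph$truth$mask)
    disp <- aortaflow:::apply_affine(T, pts) - pts
    expect_lt(mean(sqrt(rowSums(disp^2))), 1.0)
  }
  expect_error(build_shared_geometry(masks[1]), "two masks")
})

test_that("unalignable masks with full inclusion raise an atlas error", {
  # far-apart blobs: the soft-overlap objective is flat zero around every
  # start, so registration cannot bring them together and the consensus at
  # inclusion 1.0 is empty
  a <- array(FALSE, c(20, 8, 8)); a[2:6, 3:6, 3:6] <- TRUE
  b <- array(FALSE, c(20, 8, 8)); b[14:18, 3:6, 3:6] <- TRUE
  expect_error(
    suppressWarnings(build_shared_geometry(
      list(aorta_mask(a, c(1, 1, 1)), aorta_mask(b, c(1, 1, 1))), 1.0)),
    "empty")
})

test_that("mapping a subject onto itself passes values through", {
  ph <- small_tube()
  mask <- ph$truth$mask
  shared <- build_shared_geometry(list(mask, mask), 0.6)
  vals <- array(stats::rnorm(prod(dim(mask$data))), dim(mask$data))
  mapped <- map_subject(vals, mask, shared, "volume",
                        init = shared$transforms[[1]])
  loc <- which(shared$mask$data)
  ok <- !is.na(mapped)
  expect_gt(mean(ok), 0.95)
  expect_gt(mean(mapped[ok] == vals[loc][ok]), 0.90)
  # constant fields stay constant wherever covered
  ones <- map_subject(array(1, dim(mask$data)), mask, shared, "volume",
                      init = shared$transforms[[1]])
  expect_true(all(ones[!is.na(ones)] == 1))
})

test_that("a translated copy maps its values back onto the original", {
  # whole-voxel translation: nearest-neighbour pullback must reproduce the
  # original values exactly at matched voxels
  ph <- small_tube()
  ref_mask <- ph$truth$mask
  d <- dim(ref_mask$data)
  shift <- c(1, -1, 2) # voxels
  mov <- aortaflow:::shift3(ref_mask$data, shift[1], shift[2], shift[3],
                            fill = FALSE)
  mov_mask <- aorta_mask(mov, ref_mask$spacing)
  set.seed(5)
  vals_ref <- array(stats::rnorm(prod(d)), d)
  vals_mov <- aortaflow:::shift3(vals_ref, shift[1], shift[2], shift[3])
  shared <- build_shared_geometry(list(ref_mask, ref_mask), 0.6)
  mapped <- map_subject(vals_mov, mov_mask, shared, "volume")
  expect_gt(attr(mapped, "dice"), 0.9)
  ref_vals <- vals_ref[shared$mask$data]
  ok <- !is.na(mapped)
  expect_gt(mean(ok), 0.9)
  expect_gte(mean(mapped[ok] == ref_vals[ok]), 0.95)

  # rotated-and-translated copy: both subjects carry the same flow, so
  # their independently mapped speed fields must agree in the shared frame
  # (whichever subject the median-volume rule picks as reference)
  pair <- make_jittered_pair()
  shared2 <- build_shared_geometry(list(pair$ref$truth$mask,
                                        pair$mov$truth$mask), 0.5)
  spd_r <- sqrt(pair$ref$velocity$data[, , , 1, 5]^2 +
                  pair$ref$velocity$data[, , , 2, 5]^2 +
                  pair$ref$velocity$data[, , , 3, 5]^2)
  spd_m <- sqrt(pair$mov$velocity$data[, , , 1, 5]^2 +
                  pair$mov$velocity$data[, , , 2, 5]^2 +
                  pair$mov$velocity$data[, , , 3, 5]^2)
  m1 <- map_subject(spd_r, pair$ref$truth$mask, shared2, "volume",
                    init = shared2$transforms[[1]])
  m2 <- map_subject(spd_m, pair$mov$truth$mask, shared2, "volume",
                    init = shared2$transforms[[2]])
  ok2 <- !is.na(m1) & !is.na(m2)
  expect_gt(mean(ok2), 0.9)
  expect_gt(stats::cor(m1[ok2], m2[ok2]), 0.9)
  expect_lt(stats::median(abs(m1[ok2] - m2[ok2])), 0.1)
})

test_that("cohort averages follow the missing-data rules", {
  m1 <- c(1, 2, NA)
  m2 <- c(3, NA, NA)
  cm <- cohort_average(list(m1, m2))
  expect_equal(cm$mean[1], 2)            # two subjects with values 1 and 3
  expect_true(is.na(cm$mean[2]))         # n = 1 < 2: undefined
  expect_true(is.na(cm$mean[3]))         # nobody contributes
  expect_equal(cm$n_subjects, c(2, 1, 0))
})

test_that("maximum intensity projection commutes with max", {
  vol <- array(0, c(5, 6, 7))
  vol[2, 3, 4] <- 5
  for (ax in 1:3) {
    mip <- maximum_intensity_projection(vol, ax)
    expect_equal(sum(mip == 5), 1)
    expect_equal(max(mip), max(vol))
  }
  expect_true(all(maximum_intensity_projection(vol * 0, 2) == 0))
})

test_that("shared geometry is stable under subject permutation", {
  base <- phantom_config(grid_shape = c(18, 18, 24), spacing = c(2, 2, 2),
                         tube_radius = 7, tube_length = 36, v_max = 1,
                         noise_sigma = 0)
  masks <- lapply(1:4, function(i) {
    cfg <- base
    cfg$rigid_jitter <- list(rotation = c(1.5, -1, 0.5) * i / 2,
                             translation = c(0.8, -0.6, 0.4) * i / 2)
    generate_phantom(cfg)$truth$mask
  })
  s1 <- build_shared_geometry(masks, 0.6)
  s2 <- build_shared_geometry(masks[c(3, 1, 4, 2)], 0.6)
  diffc <- sum(xor(s1$mask$data, s2$mask$data))
  expect_lt(diffc / sum(s1$mask$data), 0.02)
})
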