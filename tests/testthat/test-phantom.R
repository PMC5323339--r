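test_that("phantom rasterization hits target volumes to within one voxel", {
  g <- voxel_grid(c(48, 48, 48), 2.5, origin = c(0, 0, 0))
  v_vox <- voxel_volume_cm3(g)
  tum <- tumour_spec(c(58.75, 58.75, 58.75), 40.0)
  ph <- build_phantom(phantom_spec(tum, g, background = 0))
  expect_lte(abs(ph$truth$table$volume_cm3 - 40.0), v_vox)
  # ground-truth volume equals member count x voxel volume exactly
  expect_equal(ph$truth$table$volume_cm3,
               sum(ph$truth$masks[[1]]$member) * v_vox)
  # activity map is piecewise constant at the tumour concentration
  expect_equal(sort(unique(as.vector(ph$activity$values))), c(0, 1))

  # ellipsoid and lumpy shapes hit their volumes too
  for (tm in list(tumour_spec(c(60, 60, 60), 20, shape = "ellipsoid",
                              axis_ratios = c(2, 1, 1)),
                  tumour_spec(c(60, 60, 60), 20, shape = "lumpy",
                              lumpy_amplitude = 0.2, lumpy_seed = 3))) {
    ph2 <- build_phantom(phantom_spec(tm, g, background = 0.5))
    expect_lte(abs(ph2$truth$table$volume_cm3 - 20), v_vox)
  }
})

test_that("phantoms without tumours are uniform and overlaps are rejected", {
  g <- voxel_grid(c(16, 16, 16))
  ph <- build_phantom(phantom_spec(list(), g, background = 2.5))
  expect_true(all(ph$activity$values == 2.5))
  expect_equal(nrow(ph$truth$table), 0)

  two <- list(tumour_spec(c(20, 20, 20), 8), tumour_spec(c(24, 20, 20), 8))
  expect_error(build_phantom(phantom_spec(two, g)), "overlap")
})

test_that("lumpy tumours are reproducible from their seed and stay round-ish", {
  g <- centred_grid(32)
  tm <- tumour_spec(c(0, 0, 0), 30, shape = "lumpy", lumpy_amplitude = 0.15,
                    lumpy_seed = 5)
  m1 <- spectseg:::rasterize_tumour(tm, g)
  m2 <- spectseg:::rasterize_tumour(tm, g)
  expect_identical(m1$member, m2$member)
  tm2 <- tm; tm2$lumpy_seed <- 6L
  m3 <- spectseg:::rasterize_tumour(tm2, g)
  expect_false(identical(m1$member, m3$member))
})

test_that("gaussian blur preserves counts away from borders", {
  g <- centred_grid(40)  # 100 mm across, object far from edges
  m <- sphere_mask(g, c(0, 0, 0), 10)
  act <- two_level_image(m, 1, 0)
  blurred <- spectseg:::gaussian_blur(act$values, g, fwhm_mm = 8)
  expect_lt(abs(sum(blurred) - sum(act$values)) / sum(act$values), 0.005)
})

test_that("reconstruction emulation is deterministic, Poisson-consistent and clips negatives", {
  g <- centred_grid(16)
  act <- two_level_image(sphere_mask(g, c(0, 0, 0), 8), 5, 0)
  act$unit <- "concentration"
  acq <- acquisition_spec(fwhm_mm = 6, count_scale = 10, seed = 42)

  # zero activity stays exactly zero
  zero <- scalar_image(array(0, g$shape), g, unit = "concentration")
  expect_true(all(simulate_reconstruction(zero, acq, 1)$values == 0))

  # same (seed, index) twice: identical; different index: different
  r1 <- simulate_reconstruction(act, acq, 3)
  r2 <- simulate_reconstruction(act, acq, 3)
  r3 <- simulate_reconstruction(act, acq, 4)
  expect_identical(r1$values, r2$values)
  expect_false(identical(r1$values, r3$values))

  # simulating must not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(simulate_reconstruction(act, acq, 1)); x2 <- runif(1)
  expect_identical(x1, x2)

  # per-voxel mean over 200 realizations within 5 SE on 99% of voxels
  ex <- expected_reconstruction(act, acq)
  acc <- array(0, g$shape)
  for (i in 1:200) acc <- acc + simulate_reconstruction(act, acq, i,
                                                        expected = ex)$values
  mean_img <- acc / 200
  se <- sqrt(pmax(ex$values, 1e-12) / 200)
  frac_ok <- mean(abs(mean_img - ex$values) <= 5 * se | ex$values == 0)
  expect_gt(frac_ok, 0.99)

  # edge enhancement overshoots at the border and never goes negative
  acq_asr <- acquisition_spec(fwhm_mm = 6, count_scale = 10,
                              edge_enhancement = 0.8, seed = 42)
  ex_asr <- expected_reconstruction(act, acq_asr)
  expect_true(all(ex_asr$values >= 0))
  expect_gt(max(ex_asr$values), max(ex$values))
})

test_that("initialization VOIs add the requested margin and clip at borders", {
  g <- centred_grid(24)
  truth <- sphere_mask(g, c(0, 0, 0), 10)
  expect_identical(make_initialization_voi(truth, 0)$member, truth$member)

  voi <- make_initialization_voi(truth, 5)
  expect_true(all(voi$member[truth$member]))
  # all added voxels within 2 voxels of the truth (margin 5 mm / 2.5 mm grid)
  outer2 <- spectseg:::box_morph(truth$member, c(2L, 2L, 2L), "dilate")
  expect_true(all(voi$member == outer2))

  big <- make_initialization_voi(truth, 500)
  expect_equal(sum(big$member), prod(g$shape))
})

test_that("RC calibration phantoms centre spheres in a cold background", {
  phs <- rc_phantom(c(1, 4, 16, 64))
  expect_length(phs, 4)
  for (i in seq_along(phs)) {
    p <- phs[[i]]
    v_vox <- voxel_volume_cm3(p$activity$grid)
    expect_lte(abs(p$volume_cm3 - c(1, 4, 16, 64)[i]), v_vox)
    expect_true(all(p$activity$values[!p$true_mask$member] == 0))
    expect_true(all(p$activity$values[p$true_mask$member] == 1))
  }
  expect_error(rc_phantom(1e6), "fit")
})
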