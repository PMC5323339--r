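test_that("voxel grid validates its geometry", {
  g <- voxel_grid(c(4, 5, 6), spacing = c(1, 2, 3), origin = c(-1, 0, 1))
  expect_equal(g$shape, c(4L, 5L, 6L))
  expect_equal(voxel_volume_cm3(g), 6 / 1000)
  expect_error(voxel_grid(c(0, 4, 4)), "positive")
  expect_error(voxel_grid(4, spacing = c(1, -1, 1)), "spacing")
  expect_error(scalar_image(array(1, c(3, 3, 3)), voxel_grid(c(4, 4, 4))),
               "shape")
  expect_error(scalar_image(array(c(1, NA), c(2, 2, 2))), "finite")
})

test_that("trilinear sampling reproduces voxel centres, interpolates linearly, and is zero outside", {
  g <- voxel_grid(c(4, 4, 4), spacing = 2, origin = c(10, 0, -4))
  set.seed(42)
  vals <- array(rnorm(64), c(4, 4, 4))
  img <- scalar_image(vals, g)
  # all voxel centres reproduce the lattice exactly
  xyz <- spectseg:::grid_coordinates(g)
  expect_equal(trilinear_sample(img, xyz), as.vector(vals))
  # midpoint between two adjacent centres averages them
  p <- c(10 + 1, 0, -4)
  expect_equal(trilinear_sample(img, p), (vals[1, 1, 1] + vals[2, 1, 1]) / 2)
  # fractional position along one axis
  p <- c(10 + 0.5, 0, -4)
  expect_equal(trilinear_sample(img, p),
               0.75 * vals[1, 1, 1] + 0.25 * vals[2, 1, 1])
  # far outside and just outside the voxel-centre hull
  expect_equal(trilinear_sample(img, c(200, 0, 0)), 0)
  expect_equal(trilinear_sample(img, c(9.9, 0, -4)), 0)
})

test_that("image gradient matches the hand-derived ramp response and kernel symmetries", {
  g <- voxel_grid(c(8, 8, 8), spacing = 2)
  ramp <- array(rep(0:7, times = 64), c(8, 8, 8))  # I(i,j,k) = i
  gr <- image_gradient(scalar_image(ramp, g))
  # slope 1 per index = 1 per 2 mm = 0.5 per mm in the interior
  expect_equal(gr$x[2:7, 2:7, 2:7], array(0.5, c(6, 6, 6)))
  expect_equal(gr$y[2:7, 2:7, 2:7], array(0, c(6, 6, 6)))
  expect_equal(gr$z[2:7, 2:7, 2:7], array(0, c(6, 6, 6)))

  # constant image: zero field everywhere (including borders)
  gc <- image_gradient(scalar_image(array(7, c(4, 4, 4)),
                                    voxel_grid(c(4, 4, 4))))
  expect_true(all(gc$x == 0) && all(gc$y == 0) && all(gc$z == 0))

  # gradient of f + constant equals gradient of f
  set.seed(7)
  f <- array(rnorm(5^3), c(5, 5, 5))
  g5 <- voxel_grid(c(5, 5, 5))
  g1 <- image_gradient(scalar_image(f, g5))
  g2 <- image_gradient(scalar_image(f + 13.5, g5))
  expect_equal(g1$x, g2$x)
  expect_equal(g1$y, g2$y)
  expect_equal(g1$z, g2$z)

  # mirroring along x negates and mirrors the x-component (antisymmetry)
  fm <- f[5:1, , ]
  gm <- image_gradient(scalar_image(fm, g5))
  expect_equal(gm$x, -g1$x[5:1, , ])
  expect_error(image_gradient(scalar_image(array(1, c(2, 4, 4)),
                                           voxel_grid(c(2, 4, 4)))),
               "at least 3")
})

test_that("binary closing fills interior holes and leaves solids unchanged", {
  g <- voxel_grid(c(10, 10, 10))
  cube <- array(FALSE, c(10, 10, 10))
  cube[3:8, 3:8, 3:8] <- TRUE
  m <- binary_mask(cube, g)
  expect_equal(binary_closing(m)$member, cube)

  holed <- cube
  holed[5, 5, 5] <- FALSE
  expect_equal(binary_closing(binary_mask(holed, g))$member, cube)

  empty <- binary_mask(array(FALSE, c(10, 10, 10)), g)
  expect_equal(sum(binary_closing(empty)$member), 0)
})

test_that("solidify fills shells, keeps only the seed component, and is idempotent", {
  g <- centred_grid(16)
  ball <- sphere_mask(g, c(0, 0, 0), 12)
  shell <- binary_mask(ball$member & !sphere_mask(g, c(0, 0, 0), 7)$member, g)
  filled <- solidify(shell, c(0, 0, 0))
  expect_equal(filled$member, ball$member)

  # two disjoint blobs: only the seeded one survives
  two <- binary_mask(sphere_mask(g, c(-10, 0, 0), 5)$member |
                       sphere_mask(g, c(10, 0, 0), 5)$member, g)
  kept <- solidify(two, c(-10, 0, 0))
  expect_equal(kept$member, sphere_mask(g, c(-10, 0, 0), 5)$member)

  # already-solid blob unchanged; idempotence
  expect_equal(solidify(ball, c(0, 0, 0))$member, ball$member)
  expect_equal(solidify(filled, c(0, 0, 0))$member, filled$member)

  # seed in background: empty result with degenerate flag
  expect_warning(res <- solidify(shell, c(17, 17, 17)), "background")
  expect_equal(sum(res$member), 0)
  expect_true(isTRUE(attr(res, "degenerate")))
  expect_error(solidify(shell, c(100, 0, 0)), "inside the grid")
})

test_that("dilate_mask adds a metric margin clipped at the border", {
  g <- centred_grid(16)
  m <- sphere_mask(g, c(0, 0, 0), 6)
  expect_equal(dilate_mask(m, 0)$member, m$member)
  d <- dilate_mask(m, 5)
  expect_true(all(d$member[m$member]))
  # added voxels stay within 2 voxels (Chebyshev) of the original mask
  far <- !spectseg:::box_morph(m$member, c(2L, 2L, 2L), "dilate")
  expect_false(any(d$member & far))
  # very large margin fills the grid (clipped, no error)
  expect_equal(sum(dilate_mask(m, 1000)$member), prod(g$shape))
})

test_that("largest_component keeps the biggest 6-connected island", {
  g <- centred_grid(16)
  blobs <- binary_mask(sphere_mask(g, c(-9, 0, 0), 6)$member |
                         sphere_mask(g, c(12, 0, 0), 3)$member, g)
  keep <- largest_component(blobs)
  expect_equal(keep$member, sphere_mask(g, c(-9, 0, 0), 6)$member)
})
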