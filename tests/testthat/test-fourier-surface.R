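test_that("surface evaluation reproduces constants, spheres, and closes at the poles", {
  # only the constant coefficients: every (u, v) maps to the centre
  s0 <- fourier_surface(2)
  s0$coef[1, ] <- c(1, 2, 3)
  pts <- evaluate_surface(s0, runif(5, 0, 2 * pi), runif(5, 0, pi))
  expect_equal(pts, matrix(rep(c(1, 2, 3), each = 5), 5, 3,
                           dimnames = list(NULL, c("x", "y", "z"))))

  # unit-sphere coefficients: substitute (u = 0, v = pi/2) -> (r, 0, 0)
  r <- 3.7
  s <- sphere_surface(r = r)
  expect_equal(as.numeric(evaluate_surface(s, 0, pi / 2)), c(r, 0, 0),
               tolerance = 1e-12)
  expect_equal(as.numeric(evaluate_surface(s, pi / 2, pi / 2)), c(0, r, 0),
               tolerance = 1e-12)
  # at v = 0 every u gives the same pole point (0, 0, r)
  pole <- evaluate_surface(s, seq(0, 5, length.out = 7), 0)
  expect_equal(pole, matrix(rep(c(0, 0, r), each = 7), 7, 3,
                            dimnames = list(NULL, c("x", "y", "z"))),
               tolerance = 1e-12)

  # pole closure for random coefficient sets, both poles
  for (seed in 1:10) {
    rs <- random_surface(K = 4, seed = seed)
    for (v in c(0, pi)) {
      pp <- evaluate_surface(rs, seq(0, 2 * pi, length.out = 9), v)
      expect_lt(max(apply(pp, 2, function(x) diff(range(x)))), 1e-9)
    }
  }
})

test_that("sampled unit-sphere points lie on the sphere to 1e-9 relative", {
  s <- sphere_surface(r = 1)
  sm <- spectseg:::fs_sampling(s, 36, 36)
  P <- evaluate_surface(s, sm$u, sm$v)
  expect_lt(max(abs(sqrt(rowSums(P^2)) - 1)), 1e-9)
})

test_that("translation of the constant coefficients translates every point exactly", {
  rs <- random_surface(K = 3, seed = 5)
  u <- runif(20, 0, 2 * pi); v <- runif(20, 0, pi)
  p1 <- evaluate_surface(rs, u, v)
  shift <- c(4.5, -2, 11)
  rs$coef[1, ] <- rs$coef[1, ] + shift
  p2 <- evaluate_surface(rs, u, v)
  expect_equal(p2, p1 + rep(shift, each = 20))
})

test_that("surface normals are radial on spheres, zero at poles, and area-consistent", {
  r <- 2.5
  s <- sphere_surface(r = r)
  u <- runif(12, 0, 2 * pi); v <- runif(12, 0.1, pi - 0.1)
  P <- evaluate_surface(s, u, v)
  nrm <- surface_normal(s, u, v)
  cosang <- rowSums(P * nrm) / (sqrt(rowSums(P^2)) * sqrt(rowSums(nrm^2)))
  expect_equal(cosang, rep(1, 12), tolerance = 1e-9)  # outward radial
  expect_equal(sqrt(rowSums(nrm^2)), r^2 * sin(v), tolerance = 1e-9)
  expect_equal(as.numeric(surface_normal(s, 1, 0)), c(0, 0, 0))
  # degenerate all-constant surface: zero normal everywhere
  s0 <- fourier_surface(2); s0$coef[1, ] <- c(1, 1, 1)
  expect_equal(max(abs(surface_normal(s0, u, v))), 0)
  # area of the unit sphere from a 72 x 72 sampling
  expect_equal(surface_area(sphere_surface(r = 1), 72, 72), 4 * pi,
               tolerance = 0.01)
})

test_that("ellipsoid coefficients trace the ellipsoid and shift linearly", {
  # unit sphere: the three classic coefficient values
  s <- sphere_surface(r = 1)
  lay <- fs_layout(2)
  expect_equal(unname(s$coef[lay$term == "a01", "z"]), 0.5)
  expect_equal(unname(s$coef[lay$term == "cml" & lay$m == 1 & lay$l == 1,
                             "x"]), 0.25)
  expect_equal(unname(s$coef[lay$term == "dml" & lay$m == 1 & lay$l == 1,
                             "y"]), 0.25)

  # rotated ellipsoid: sampled points satisfy the implicit equation to 1e-9
  th <- 0.6
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  e <- ellipsoid_init(c(5, -3, 2), rot, c(30, 20, 10))
  se <- ellipsoid_to_coefficients(e)
  sm <- spectseg:::fs_sampling(se, 36, 36)
  P <- evaluate_surface(se, sm$u, sm$v)
  local <- sweep(P, 2, e$centre) %*% e$rotation
  implicit <- rowSums(sweep(local, 2, e$semi_axes, "/")^2)
  expect_lt(max(abs(implicit - 1)), 1e-9)

  # identity rotation, centre (5, 0, 0): only a_{x,0,0} changes
  s1 <- ellipsoid_to_coefficients(ellipsoid_init(c(0, 0, 0), diag(3),
                                                 c(3, 2, 1)))
  s2 <- ellipsoid_to_coefficients(ellipsoid_init(c(5, 0, 0), diag(3),
                                                 c(3, 2, 1)))
  diffc <- s2$coef - s1$coef
  expect_equal(diffc[1, ], c(x = 5, y = 0, z = 0))
  expect_equal(max(abs(diffc[-1, ])), 0)
})

test_that("initial ellipsoid estimation recovers centre, size and orientation", {
  g <- centred_grid(24)
  truth <- sphere_mask(g, c(1, -1, 0.5), 15)
  img <- two_level_image(truth, 100, 0)
  voi <- dilate_mask(truth, 7.5)
  e <- estimate_initial_ellipsoid(img, voi)
  expect_lt(max(abs(e$centre - c(1, -1, 0.5))), 0.5 * 2.5)
  expect_true(all(abs(e$semi_axes - 15) / 15 < 0.1))

  # axis-aligned 3:2:1 ellipsoid: principal directions within 5 degrees
  g2 <- centred_grid(32)
  tr2 <- ellipsoid_mask(g2, c(0, 0, 0), c(30, 20, 10))
  img2 <- two_level_image(tr2, 50, 0)
  e2 <- estimate_initial_ellipsoid(img2, dilate_mask(tr2, 5))
  for (a in 1:3) {
    axis_world <- abs(e2$rotation[, order(-e2$semi_axes)[a]])
    expect_gt(axis_world[a], cos(5 * pi / 180))
  }

  # uniform image inside the VOI: degenerate histogram
  uni <- scalar_image(array(3, g$shape), g)
  expect_error(estimate_initial_ellipsoid(uni, voi), "degenerate")
})

test_that("edge-strength objective is zero without gradients, conservative for delta == 1, and peaks at the true edge", {
  g <- centred_grid(32)
  flat <- image_gradient(scalar_image(array(1, g$shape), g))
  s <- sphere_surface(r = 20)
  expect_equal(as.numeric(objective_B(s, flat)), 0)

  # spatially constant gradient + delta forced to 1: the numerator is a
  # discrete closed-surface flux. It cancels exactly (to rounding) for
  # ellipsoids, and for general surfaces it decays quadratically with the
  # sampling density.
  const_grad <- flat
  const_grad$x[] <- 0.7; const_grad$y[] <- -0.3; const_grad$z[] <- 1.1
  gmag <- sqrt(sum(c(0.7, 0.3, 1.1)^2))
  cfg <- objective_config(alpha = 0)
  th <- 0.5
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ell <- ellipsoid_to_coefficients(ellipsoid_init(c(3, -2, 5), rot,
                                                  c(18, 12, 9)))
  # relative flux residual: |sum g.n| / (sum |n| * |g|)
  rel_flux <- function(surface, n) {
    b <- objective_B(surface, const_grad,
                     objective_config(alpha = 0, n_u = n, n_v = n),
                     delta_mode = "one")
    abs(as.numeric(b)) * (2 * pi / n) * (pi / n) / (attr(b, "area") * gmag)
  }
  expect_lt(rel_flux(ell, 36), 1e-9)
  for (seed in 1:5) {
    rs <- random_surface(K = 3, scale = 12, seed = seed)
    r36 <- rel_flux(rs, 36)
    r72 <- rel_flux(rs, 72)
    # small residual, shrinking ~4x per sampling doubling
    expect_lt(r36, 1e-3)
    expect_lt(r72, 0.35 * r36 + 1e-12)
  }

  # sharp-edged bright sphere: B maximal on the surface at the true radius
  R <- 20
  img <- two_level_image(sphere_mask(g, c(0, 0, 0), R), 100, 0)
  grad <- image_gradient(img)
  bs <- vapply(c(0.5, 1, 1.5), function(f) {
    as.numeric(objective_B(sphere_surface(r = f * R), grad))
  }, numeric(1))
  expect_equal(which.max(bs), 2L)

  # degenerate surface: zero area errors out
  s0 <- fourier_surface(2)
  expect_error(objective_B(s0, grad), "degenerate")
})

test_that("surface optimization never returns a worse objective than its start", {
  g <- centred_grid(24)
  img <- two_level_image(sphere_mask(g, c(0, 0, 0), 15), 100, 0)
  blur <- expected_reconstruction(scalar_image(img$values, g,
                                               unit = "concentration"),
                                  acquisition_spec(fwhm_mm = 7.5,
                                                   count_scale = 1))
  grad <- image_gradient(blur)
  init <- ellipsoid_init(c(0, 0, 0), diag(3), c(14, 14, 14))
  out <- optimize_surface(blur, init, optimizer_config(max_order = 3),
                          gradient = grad)
  b_init <- objective_B(ellipsoid_to_coefficients(init), grad)
  expect_gte(attr(out, "objective"), as.numeric(b_init))
  expect_true(all(diff(attr(out, "trace")) > -1e-9))
})

test_that("voxelization reproduces analytic volumes and repairs folded surfaces", {
  # sphere r = 25 mm on a 2.5 mm grid: volume within 2% of 65.45 cm^3
  g <- centred_grid(48)
  m <- voxelize_surface(sphere_surface(r = 25), g)
  expect_equal(mask_volume_cm3(m), 4 / 3 * pi * 25^3 / 1000, tolerance = 0.02)

  # ellipsoid with all semi-axes >= 5 voxels: within 2% of (4/3) pi r1 r2 r3
  e <- ellipsoid_init(c(0, 0, 0), diag(3), c(30, 20, 12.5))
  me <- voxelize_surface(ellipsoid_to_coefficients(e), g)
  expect_equal(mask_volume_cm3(me), 4 / 3 * pi * 30 * 20 * 12.5 / 1000,
               tolerance = 0.02)

  # a large high-order coefficient folds the surface; the repaired mask is
  # solid (solidify idempotent) and a single 6-connected component
  s <- sphere_surface(r = 15)
  while (s$K < 4) s <- spectseg:::fs_promote(s)
  lay <- fs_layout(4)
  s$coef[which(lay$term == "cml" & lay$m == 3 & lay$l == 3)[1], 1] <- 6
  mf <- voxelize_surface(s, g)
  expect_equal(solidify(mf, c(0, 0, 0))$member, mf$member)
  lab <- spectseg:::cpp_label_components(as.logical(mf$member), g$shape)
  expect_equal(length(unique(lab[lab > 0])), 1L)

  # sub-voxel surface: minimal-mask policy gives the single centre voxel
  tiny <- sphere_surface(centre = c(1, 1, 1), r = 0.4)
  mt <- voxelize_surface(tiny, centred_grid(8))
  expect_equal(sum(mt$member), 1)
  ci <- which(mt$member, arr.ind = TRUE)
  expect_equal(as.numeric(spectseg:::grid_coordinates(mt$grid)[
    which(as.vector(mt$member)), ]), c(1.25, 1.25, 1.25))

  # surface fully outside the grid errors
  far <- sphere_surface(centre = c(500, 0, 0), r = 5)
  expect_error(voxelize_surface(far, centred_grid(8)), "outside")
})

test_that("voxelized ellipsoid volumes converge as the grid is refined", {
  vol_err <- function(spacing) {
    n <- ceiling(70 / spacing)
    g <- voxel_grid(rep(n, 3), spacing, origin = rep(-spacing * (n - 1) / 2, 3))
    e <- ellipsoid_init(c(0, 0, 0), diag(3), c(25, 18, 15))
    v <- mask_volume_cm3(voxelize_surface(ellipsoid_to_coefficients(e), g))
    abs(v - 4 / 3 * pi * 25 * 18 * 15 / 1000) / (4 / 3 * pi * 25 * 18 * 15 / 1000)
  }
  e3 <- vol_err(3)
  e2 <- vol_err(2)
  expect_lt(e3, 0.02)
  expect_lt(e2, 0.02)
})

test_that("fs_segment recovers a blurred sphere and rejects empty VOIs", {
  g <- centred_grid(40)
  truth <- sphere_mask(g, c(0, 0, 0), 17)
  act <- two_level_image(truth, 1, 0)
  act$unit <- "concentration"
  img <- expected_reconstruction(act, acquisition_spec(fwhm_mm = 10,
                                                       count_scale = 100))
  voi <- make_initialization_voi(truth, 10)
  mask <- fs_segment(img, voi)
  d <- dice_cross_grid(mask, truth)
  expect_gt(d$dsc, 0.85)
  expect_error(fs_segment(img, binary_mask(array(FALSE, g$shape), g)),
               "empty")
})

test_that("surface JSON and point-cloud exports round-trip", {
  rs <- random_surface(K = 3, seed = 9)
  f <- tempfile(fileext = ".json")
  write_surface_json(rs, f)
  back <- read_surface_json(f)
  expect_equal(back$K, rs$K)
  expect_equal(back$coef, rs$coef, tolerance = 1e-12)
  pts <- surface_points(rs, 12, 6)
  expect_equal(nrow(pts), 72)
  expect_equal(unname(as.matrix(pts[, c("x", "y", "z")])),
               unname(evaluate_surface(rs, pts$u, pts$v)))
})
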