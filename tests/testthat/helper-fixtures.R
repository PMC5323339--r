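# Shared fixtures: all test data are generated in code.

# cubic grid centred on the origin
centred_grid <- function(n, spacing = 2.5) {
  voxel_grid(rep(n, 3), spacing = spacing,
             origin = rep(-spacing * (n - 1) / 2, 3))
}

# binary sphere/ellipsoid mask by voxel-centre membership
ellipsoid_mask <- function(grid, centre, semi_axes) {
  xyz <- spectseg:::grid_coordinates(grid)
  rel <- sweep(xyz, 2, centre)
  inside <- rowSums(sweep(rel, 2, semi_axes, "/")^2) <= 1
  binary_mask(array(inside, grid$shape), grid)
}

sphere_mask <- function(grid, centre, r) ellipsoid_mask(grid, centre, rep(r, 3))

# piecewise-constant image: `inside` value on a mask, `outside` elsewhere
two_level_image <- function(mask, inside = 100, outside = 0) {
  vals <- array(outside, mask$grid$shape)
  vals[mask$member] <- inside
  scalar_image(vals, mask$grid)
}

# exact Fourier-surface coefficients of an axis-aligned sphere
sphere_surface <- function(centre = c(0, 0, 0), r = 1) {
  ellipsoid_to_coefficients(ellipsoid_init(centre, diag(3), rep(r, 3)))
}

# random surface with bounded higher-order perturbations (for property tests)
random_surface <- function(K = 3, scale = 20, seed = 1) {
  set.seed(seed)
  s <- ellipsoid_to_coefficients(
    ellipsoid_init(stats::runif(3, -10, 10), diag(3),
                   stats::runif(3, 0.6, 1.4) * scale))
  while (s$K < K) s <- spectseg:::fs_promote(s)
  pert <- matrix(stats::rnorm(length(s$coef), sd = 0.03 * scale),
                 nrow(s$coef), 3)
  pert[1:2, ] <- 0
  fourier_surface(K, s$coef + pert)
}

# point-in-mask test: which cuboid (if any) contains each point
mask_contains <- function(mask, pts) {
  g <- mask$grid
  idx <- round(sweep(sweep(pts, 2, g$origin, "-"), 2, g$spacing, "/"))
  ok <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
    idx[, 1] < g$shape[1] & idx[, 2] < g$shape[2] & idx[, 3] < g$shape[3]
  out <- logical(nrow(pts))
  lin <- idx[ok, 1] + g$shape[1] * (idx[ok, 2] + g$shape[2] * idx[ok, 3]) + 1
  out[ok] <- as.vector(mask$member)[lin]
  out
}

# brute-force Otsu: evaluate every unique-value split directly
otsu_brute_force <- function(values) {
  u <- sort(unique(values))
  n <- length(values)
  best <- -Inf
  best_t <- u[1]
  for (t in u[-length(u)]) {
    lo <- values[values <= t]
    hi <- values[values > t]
    w0 <- length(lo) / n
    w1 <- length(hi) / n
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-15) {
      best <- bcv
      best_t <- t
    }
  }
  best_t
}
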