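#' Fourier-descriptor surfaces
#'
#' A closed surface is parameterized by truncated Fourier series in two
#' surface coordinates, `u` in `[0, 2*pi)` around the object and `v` in
#' `[0, pi]` from pole to pole. Each Cartesian coordinate `q` in `{x, y, z}`
#' is expanded as
#'
#' `q(u,v) = a_{q,0,0} + 2 a_{q,0,1} cos(v) + 2 sum_l c_{q,0,l} sin(l v)
#'          + 4 sum_{m,l} [ c_{q,m,l} cos(m u) sin(l v)
#'                        + d_{q,m,l} sin(m u) sin(l v) ]`
#'
#' with wave numbers `m = 1..K-1` and `l = 1..K-1` for a surface of order `K`
#' (the u- and v-order are kept equal). All `sin(l v)` terms vanish at the
#' poles `v = 0, pi`, so the surface closes there by construction. The
#' coefficient triple `(a_{x,0,0}, a_{y,0,0}, a_{z,0,0})` sets the global
#' surface position and is used as the interior seed point downstream.
#'
#' @param K Integer order, `>= 2`.
#' @param coef Coefficient matrix with `fs_ncoef(K)` rows and columns
#'   `x, y, z` (mm); rows are ordered as in [fs_layout()]. Defaults to zeros.
#' @return An object of class `fourier_surface`.
#' @export
fourier_surface <- function(K, coef = NULL) {
  K <- as.integer(K)
  if (K < 2) stop("surface order K must be >= 2")
  p <- fs_ncoef(K)
  if (is.null(coef)) coef <- matrix(0, p, 3)
  coef <- as.matrix(coef)
  if (!all(dim(coef) == c(p, 3))) {
    stop(sprintf("coef must be a %d x 3 matrix for K = %d", p, K))
  }
  colnames(coef) <- c("x", "y", "z")
  structure(list(K = K, coef = coef), class = "fourier_surface")
}

#' @rdname fourier_surface
#' @export
fs_ncoef <- function(K) 2L + (K - 1L) + 2L * (K - 1L)^2

#' @rdname fourier_surface
#' @export
fs_layout <- function(K) {
  K <- as.integer(K)
  term <- c("a00", "a01", rep("c0l", K - 1))
  m <- c(0L, 0L, rep(0L, K - 1))
  l <- c(0L, 1L, seq_len(K - 1))
  for (mm in seq_len(K - 1)) {
    for (ll in seq_len(K - 1)) {
      term <- c(term, "cml", "dml")
      m <- c(m, mm, mm)
      l <- c(l, ll, ll)
    }
  }
  data.frame(term = term, m = m, l = l)
}

#' @export
print.fourier_surface <- function(x, ...) {
  cat(sprintf("<fourier_surface> order K = %d (%d coefficients per coordinate)\n",
              x$K, nrow(x$coef)))
  cat(sprintf("  centre point (%.2f, %.2f, %.2f) mm\n",
              x$coef[1, 1], x$coef[1, 2], x$coef[1, 3]))
  invisible(x)
}

# basis matrices for nodes (u, v): value and partial derivatives wrt u and v
fs_basis <- function(u, v, K) {
  n <- length(u)
  stopifnot(length(v) == n)
  p <- fs_ncoef(K)
  val <- du <- dv <- matrix(0, n, p)
  val[, 1] <- 1
  val[, 2] <- 2 * cos(v)
  dv[, 2] <- -2 * sin(v)
  col <- 2L
  for (ll in seq_len(K - 1)) {
    col <- col + 1L
    val[, col] <- 2 * sin(ll * v)
    dv[, col] <- 2 * ll * cos(ll * v)
  }
  for (mm in seq_len(K - 1)) {
    cmu <- cos(mm * u); smu <- sin(mm * u)
    for (ll in seq_len(K - 1)) {
      slv <- sin(ll * v); clv <- cos(ll * v)
      col <- col + 1L
      val[, col] <- 4 * cmu * slv
      du[, col] <- -4 * mm * smu * slv
      dv[, col] <- 4 * ll * cmu * clv
      col <- col + 1L
      val[, col] <- 4 * smu * slv
      du[, col] <- 4 * mm * cmu * slv
      dv[, col] <- 4 * ll * smu * clv
    }
  }
  list(val = val, du = du, dv = dv)
}

#' Evaluate a Fourier surface
#'
#' @param surface A [fourier_surface()].
#' @param u,v Surface coordinates (radians); recycled to a common length.
#'   `u` is wrapped modulo `2*pi`, `v` is clamped to `[0, pi]`.
#' @return An `n x 3` matrix of world points (mm).
#' @export
evaluate_surface <- function(surface, u, v) {
  n <- max(length(u), length(v))
  u <- rep_len(u, n) %% (2 * pi)
  v <- pmin(pmax(rep_len(v, n), 0), pi)
  pts <- fs_basis(u, v, surface$K)$val %*% surface$coef
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' Surface normal of a Fourier surface
#'
#' Cross product of the analytic partial derivatives `dr/du x dr/dv`. The
#' magnitude is the local area element, so summing `|n| du dv` over a sample
#' lattice approximates the surface area. The orientation is corrected to
#' point away from the surface's centre coefficient point; the normal is the
#' zero vector at the poles.
#'
#' @inheritParams evaluate_surface
#' @return An `n x 3` matrix of (unnormalized) outward normals (mm^2).
#' @export
surface_normal <- function(surface, u, v) {
  n <- max(length(u), length(v))
  u <- rep_len(u, n) %% (2 * pi)
  v <- pmin(pmax(rep_len(v, n), 0), pi)
  b <- fs_basis(u, v, surface$K)
  P <- b$val %*% surface$coef
  Du <- b$du %*% surface$coef
  Dv <- b$dv %*% surface$coef
  nrm <- cbind(Du[, 2] * Dv[, 3] - Du[, 3] * Dv[, 2],
               Du[, 3] * Dv[, 1] - Du[, 1] * Dv[, 3],
               Du[, 1] * Dv[, 2] - Du[, 2] * Dv[, 1])
  centre <- surface$coef[1, ]
  flip <- rowSums(nrm * sweep(P, 2, centre)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  colnames(nrm) <- c("x", "y", "z")
  nrm
}

# midpoint sample lattice over (u, v); poles excluded so normals are nonzero
fs_sampling <- function(surface, n_u, n_v) {
  u1 <- 2 * pi * (seq_len(n_u) - 1) / n_u
  v1 <- pi * (seq_len(n_v) - 0.5) / n_v
  u <- rep(u1, times = n_v)
  v <- rep(v1, each = n_u)
  list(u = u, v = v, du = 2 * pi / n_u, dv = pi / n_v, n_u = n_u, n_v = n_v)
}

#' Surface area by sampled normals
#' @inheritParams evaluate_surface
#' @param n_u,n_v Sample counts along `u` and `v`.
#' @return Approximate surface area (mm^2).
#' @export
surface_area <- function(surface, n_u = 72, n_v = 72) {
  s <- fs_sampling(surface, n_u, n_v)
  nrm <- surface_normal(surface, s$u, s$v)
  sum(sqrt(rowSums(nrm^2))) * s$du * s$dv
}

#' Ellipsoid initialization
#'
#' @param centre World centre (mm).
#' @param rotation Proper rotation matrix (columns = ellipsoid axes in world
#'   coordinates).
#' @param semi_axes Positive semi-axis lengths (mm) along the rotated axes.
#' @return An object of class `ellipsoid_init`.
#' @export
ellipsoid_init <- function(centre, rotation = diag(3), semi_axes) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation must be orthonormal")
  }
  if (det(rotation) < 0) stop("rotation must be proper (det = +1)")
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  structure(list(centre = as.numeric(centre), rotation = rotation,
                 semi_axes = as.numeric(semi_axes)),
            class = "ellipsoid_init")
}

#' Exact order-2 surface tracing an ellipsoid
#'
#' In the ellipsoid frame the spherical parameterization maps onto the basis
#' with `a_{z,0,1} = r3/2`, `c_{x,1,1} = r1/4`, `d_{y,1,1} = r2/4`; because the
#' basis is linear in the coefficients, the world-frame surface is obtained by
#' applying the rotation coefficient-wise across the x/y/z coefficient
#' families and adding the centre to the constant terms.
#'
#' @param e An [ellipsoid_init()].
#' @return A [fourier_surface()] of order 2.
#' @export
ellipsoid_to_coefficients <- function(e) {
  p <- fs_ncoef(2L)
  local <- matrix(0, p, 3)
  lay <- fs_layout(2L)
  i_a01 <- which(lay$term == "a01")
  i_c11 <- which(lay$term == "cml" & lay$m == 1 & lay$l == 1)
  i_d11 <- which(lay$term == "dml" & lay$m == 1 & lay$l == 1)
  local[i_a01, 3] <- e$semi_axes[3] / 2
  local[i_c11, 1] <- e$semi_axes[1] / 4
  local[i_d11, 2] <- e$semi_axes[2] / 4
  world <- local %*% t(e$rotation)
  world[1, ] <- e$centre
  fourier_surface(2L, world)
}

#' Initial ellipsoid estimate from the image
#'
#' Pipeline behind the deformable-surface initialization: Otsu thresholding
#' within the initialization VOI, a morphological closing, retention of the
#' largest 6-connected component, centre of mass of the binary object, axis
#' directions from the Hotelling transform (principal components of the
#' member-voxel world coordinates), and semi-axis lengths chosen by downhill
#' simplex to include as many object voxels as possible while excluding
#' non-object VOI voxels.
#'
#' @inheritParams fixed_threshold_segment
#' @return An [ellipsoid_init()] with attribute `binary_object` (the
#'   post-closing object mask).
#' @export
estimate_initial_ellipsoid <- function(image, init_voi) {
  seg <- otsu_segment(image, init_voi)
  obj <- binary_closing(seg$mask)
  obj <- largest_component(obj)
  if (!any(obj$member)) stop("empty object after closing")
  coords <- grid_coordinates(obj$grid)[as.vector(obj$member), , drop = FALSE]
  centre <- colMeans(coords)
  centred <- sweep(coords, 2, centre)
  if (nrow(coords) > 3) {
    eg <- eigen(stats::cov(coords), symmetric = TRUE)
    rot <- eg$vectors
    if (det(rot) < 0) rot[, 3] <- -rot[, 3]
    sdev <- sqrt(pmax(eg$values, 0))
  } else {
    rot <- diag(3)
    sdev <- rep(mean(obj$grid$spacing), 3)
  }
  # uniform solid ellipsoid: sd along an axis = r / sqrt(5)
  start <- pmax(sqrt(5) * sdev, mean(obj$grid$spacing))
  voi_coords <- grid_coordinates(obj$grid)[as.vector(init_voi$member), ,
                                           drop = FALSE]
  voi_obj <- obj$member[init_voi$member]
  local <- sweep(voi_coords, 2, centre) %*% rot
  score <- function(logr) {
    r <- exp(logr)
    inside <- rowSums(sweep(local, 2, r, "/")^2) <= 1
    sum(inside & voi_obj) - sum(inside & !voi_obj)
  }
  opt <- stats::optim(log(start), score, method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = 400,
                                     reltol = 1e-6))
  out <- ellipsoid_init(centre, rot, exp(opt$par))
  attr(out, "binary_object") <- obj
  out
}

#' Objective configuration for the surface optimization
#'
#' @param alpha Area-normalization exponent in `[0, 1]`; 1 normalizes the
#'   summed edge strength fully by the surface area, 0 not at all. Default
#'   0.7, a value suited to low-resolution emission images where gradients
#'   alone cannot keep the surface from shrinking.
#' @param n_u,n_v Numbers of surface sample nodes along `u` and `v`
#'   (default 36 each).
#' @param polarity `"hot"` for objects brighter than their surroundings
#'   (gradient points inward at the edge), `"cold"` for the reverse.
#' @return An object of class `objective_config`.
#' @export
objective_config <- function(alpha = 0.7, n_u = 36, n_v = 36,
                             polarity = c("hot", "cold")) {
  polarity <- match.arg(polarity)
  stopifnot(alpha >= 0, alpha <= 1, n_u >= 8, n_v >= 8)
  structure(list(alpha = alpha, n_u = as.integer(n_u), n_v = as.integer(n_v),
                 polarity = polarity), class = "objective_config")
}

#' Optimizer configuration for the surface optimization
#'
#' @param max_order Highest Fourier order in the escalation schedule
#'   (2, 3, ..., `max_order`); default 4.
#' @param reltol Relative convergence tolerance of the downhill simplex and of
#'   the between-restart objective change ("did not change appreciably").
#' @param maxit Maximum simplex iterations per stage.
#' @param max_restarts Maximum simplex re-initializations per order.
#' @param step_frac Initial simplex perturbation for coefficients carried over
#'   from the previous stage, as a fraction of the mean initial semi-axis.
#' @param step_frac_new Initial perturbation for freshly appended
#'   (zero-initialized) coefficients, same scale.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(max_order = 4, reltol = 1e-3, maxit = 3000,
                             max_restarts = 5, step_frac = 0.05,
                             step_frac_new = 0.02) {
  stopifnot(max_order >= 2, reltol > 0, maxit > 0, max_restarts >= 1,
            step_frac > 0, step_frac_new > 0)
  structure(list(max_order = as.integer(max_order), reltol = reltol,
                 maxit = as.integer(maxit),
                 max_restarts = as.integer(max_restarts),
                 step_frac = step_frac, step_frac_new = step_frac_new),
            class = "optimizer_config")
}

#' Edge-strength objective of a surface against an image gradient
#'
#' Sum over surface sample nodes of the scalar product between the
#' interpolated image gradient and the outward surface normal, rectified by a
#' polarity term `delta`, and normalized by the total sampled surface area
#' raised to `alpha`. For a hot object the image gradient at the true edge
#' points inward (intensity decreases outward), so contributions with
#' `grad . n_out < 0` enter with `delta = -1` (positively) and contributions
#' of the opposite sense are discarded (`delta = 0`); the cold polarity flips
#' this.
#'
#' @param surface A [fourier_surface()].
#' @param gradient A vector field from [image_gradient()].
#' @param cfg An [objective_config()].
#' @param delta_mode `"polarity"` (default) applies the rectifying `delta` to
#'   outward-oriented normals; `"one"` forces `delta == 1` and keeps the raw
#'   cross-product normal, making the numerator a discrete closed-surface
#'   flux (for a spatially constant gradient field it vanishes as the
#'   sampling refines -- exactly so for ellipsoids).
#' @return Scalar objective value `B` (attribute `area`: sampled area, mm^2).
#' @export
objective_B <- function(surface, gradient, cfg = objective_config(),
                        delta_mode = c("polarity", "one")) {
  delta_mode <- match.arg(delta_mode)
  s <- fs_sampling(surface, cfg$n_u, cfg$n_v)
  b <- fs_basis(s$u, s$v, surface$K)
  b <- list(val = t(b$val), du = t(b$du), dv = t(b$dv))
  pol <- if (delta_mode == "one") 0L else if (cfg$polarity == "hot") 1L else -1L
  parts <- cpp_objective_parts(b$val, b$du, b$dv, surface$coef,
                               as.numeric(gradient$x), as.numeric(gradient$y),
                               as.numeric(gradient$z), gradient$grid$shape,
                               gradient$grid$spacing, gradient$grid$origin,
                               pol)
  if (parts[2] <= 0) stop("degenerate surface: zero total area")
  structure(parts[1] / parts[2]^cfg$alpha, area = parts[2] * s$du * s$dv)
}

# promote a surface to order K + 1, zero-initializing appended coefficients
fs_promote <- function(surface) {
  K2 <- surface$K + 1L
  lay_old <- fs_layout(surface$K)
  lay_new <- fs_layout(K2)
  key <- function(l) paste(l$term, l$m, l$l)
  idx <- match(key(lay_old), key(lay_new))
  coef <- matrix(0, fs_ncoef(K2), 3)
  coef[idx, ] <- surface$coef
  fourier_surface(K2, coef)
}

#' Fit a Fourier surface to an image by maximizing edge strength
#'
#' Downhill-simplex maximization of [objective_B()] with gradual order
#' escalation: starting from an order-2 ellipsoid, the simplex is run over all
#' coefficients of the current order; on convergence the order is increased by
#' one (appended coefficients start at 0) up to `opt$max_order`. Within each
#' order the simplex is re-initialized from the incumbent until the objective
#' change between consecutive re-initializations falls below `opt$reltol` or
#' `opt$max_restarts` is reached. The returned surface never has a lower
#' objective than the initialization.
#'
#' @param image A [scalar_image()].
#' @param init An [ellipsoid_init()] or a [fourier_surface()].
#' @param opt An [optimizer_config()].
#' @param cfg An [objective_config()].
#' @param gradient Optional precomputed [image_gradient()] of `image`.
#' @return The optimized [fourier_surface()] with attributes `objective` (final
#'   `B`) and `trace` (per-stage objective values).
#' @export
optimize_surface <- function(image, init, opt = optimizer_config(),
                             cfg = objective_config(), gradient = NULL) {
  if (inherits(init, "ellipsoid_init")) {
    scale0 <- mean(init$semi_axes)
    surface <- ellipsoid_to_coefficients(init)
  } else if (inherits(init, "fourier_surface")) {
    surface <- init
    scale0 <- max(mean(abs(surface$coef[-1, ])) * 4, mean(image$grid$spacing))
  } else stop("init must be an ellipsoid_init or fourier_surface")
  if (is.null(gradient)) gradient <- image_gradient(image)

  gx <- as.numeric(gradient$x)
  gy <- as.numeric(gradient$y)
  gz <- as.numeric(gradient$z)
  obj_of <- function(surface) {
    s <- fs_sampling(surface, cfg$n_u, cfg$n_v)
    b <- fs_basis(s$u, s$v, surface$K)
    b <- list(val = t(b$val), du = t(b$du), dv = t(b$dv))
    pol <- if (cfg$polarity == "hot") 1L else -1L
    function(par) {
      coef <- matrix(par, ncol = 3)
      parts <- cpp_objective_parts(b$val, b$du, b$dv, coef,
                                   gx, gy, gz,
                                   gradient$grid$shape, gradient$grid$spacing,
                                   gradient$grid$origin, pol)
      if (!is.finite(parts[1]) || !is.finite(parts[2])) {
        stop("non-finite objective during optimization")
      }
      if (parts[2] <= 0) return(-Inf)
      parts[1] / parts[2]^cfg$alpha
    }
  }

  trace <- numeric(0)
  B0 <- NULL
  repeat {
    fn <- obj_of(surface)
    par <- as.numeric(surface$coef)
    if (is.null(B0)) B0 <- fn(par)
    # R's simplex perturbs each coordinate by 0.1 * parscale when building the
    # initial simplex; scale so the step matches the configured fractions
    is_new <- as.numeric(surface$coef) == 0
    parstep <- ifelse(is_new, opt$step_frac_new, opt$step_frac) * scale0
    incumbent <- fn(par)
    for (restart in seq_len(opt$max_restarts)) {
      res <- stats::optim(par, fn, method = "Nelder-Mead",
                          control = list(fnscale = -1, maxit = opt$maxit,
                                         reltol = opt$reltol,
                                         parscale = parstep / 0.1))
      newval <- res$value
      par <- res$par
      if (abs(newval - incumbent) <=
          opt$reltol * (abs(incumbent) + opt$reltol)) {
        incumbent <- max(incumbent, newval)
        break
      }
      incumbent <- max(incumbent, newval)
    }
    surface <- fourier_surface(surface$K, matrix(par, ncol = 3))
    trace <- c(trace, incumbent)
    if (surface$K >= opt$max_order) break
    surface <- fs_promote(surface)
  }
  final <- objective_B(surface, gradient, cfg)
  if (as.numeric(final) < B0) {
    # monotone-improvement contract: never return worse than the initialization
    warning("optimization did not improve the objective; returning initialization")
    surface <- if (inherits(init, "ellipsoid_init")) {
      ellipsoid_to_coefficients(init)
    } else init
    final <- objective_B(surface, gradient, cfg)
  }
  attr(surface, "objective") <- as.numeric(final)
  attr(surface, "trace") <- trace
  surface
}

#' Voxelize the interior of a Fourier surface
#'
#' Candidate voxels (the padded bounding box of a dense surface sampling) are
#' classified as inside when the vector from the voxel centre to the nearest
#' sampled surface point has a negative scalar product with the outward
#' normal there (a tangent-plane signed-distance test, first-order accurate
#' between samples). Because high-order surfaces can fold, the raw
#' classification is repaired with [solidify()] seeded at the surface's centre
#' coefficient point: cavities are filled and islands disconnected from the
#' seed removed.
#'
#' @param surface A [fourier_surface()].
#' @param grid A [voxel_grid()].
#' @param n_u,n_v Dense sampling used for the nearest-point search.
#' @return A `binary_mask` on `grid`.
#' @export
voxelize_surface <- function(surface, grid, n_u = 144, n_v = 72) {
  s <- fs_sampling(surface, n_u, n_v)
  P <- evaluate_surface(surface, s$u, s$v)
  nrm <- surface_normal(surface, s$u, s$v)
  lo <- apply(P, 2, min) - 2 * grid$spacing
  hi <- apply(P, 2, max) + 2 * grid$spacing
  ilo <- pmax(floor((lo - grid$origin) / grid$spacing), 0)
  ihi <- pmin(ceiling((hi - grid$origin) / grid$spacing), grid$shape - 1)
  if (any(ihi < 0) || any(ilo > grid$shape - 1)) {
    stop("surface lies entirely outside the grid")
  }
  member <- array(FALSE, grid$shape)
  centre <- surface$coef[1, ]
  # minimal-mask policy: a sub-voxel surface yields the voxel holding its centre
  ext <- apply(P, 2, function(x) diff(range(x)))
  if (all(ext < grid$spacing)) {
    ci <- round((centre - grid$origin) / grid$spacing)
    if (all(ci >= 0) && all(ci < grid$shape)) {
      member[ci[1] + 1, ci[2] + 1, ci[3] + 1] <- TRUE
      return(binary_mask(member, grid))
    }
  }
  ax <- lapply(1:3, function(a) ilo[a]:ihi[a])
  vox <- cbind(
    rep(ax[[1]], times = length(ax[[2]]) * length(ax[[3]])),
    rep(rep(ax[[2]], each = length(ax[[1]])), times = length(ax[[3]])),
    rep(ax[[3]], each = length(ax[[1]]) * length(ax[[2]]))
  )
  centres <- sweep(sweep(vox, 2, grid$spacing, "*"), 2, grid$origin, "+")
  inside <- cpp_classify_inside(centres, P, nrm, n_u, n_v, 4L)
  member[vox + 1] <- inside
  if (!any(member)) {
    ci <- round((centre - grid$origin) / grid$spacing)
    if (all(ci >= 0) && all(ci < grid$shape)) {
      member[ci[1] + 1, ci[2] + 1, ci[3] + 1] <- TRUE
      return(binary_mask(member, grid))
    }
    stop("voxelized surface is empty on this grid")
  }
  seed <- pmin(pmax(centre, grid$origin),
               grid$origin + (grid$shape - 1) * grid$spacing)
  suppressWarnings(out <- solidify(binary_mask(member, grid), seed))
  if (!any(out$member)) {
    # seed fell outside the classified set; fall back to the raw classification
    out <- binary_mask(member, grid)
  }
  out
}

#' Read and write Fourier-surface coefficients as JSON
#'
#' The JSON object stores the order `K` and the per-coordinate coefficient
#' vectors in [fs_layout()] order.
#'
#' @param surface A [fourier_surface()].
#' @param path File path.
#' @return `read_surface_json()` returns a [fourier_surface()].
#' @export
write_surface_json <- function(surface, path) {
  obj <- list(K = surface$K, x = surface$coef[, 1], y = surface$coef[, 2],
              z = surface$coef[, 3])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surface_json
#' @export
read_surface_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fourier_surface(obj$K, cbind(obj$x, obj$y, obj$z))
}

#' Sampled surface point cloud
#'
#' @param surface A [fourier_surface()].
#' @param n_u,n_v Sample counts.
#' @return A tibble with columns `u`, `v`, `x`, `y`, `z` (suitable for CSV
#'   export).
#' @export
surface_points <- function(surface, n_u = 72, n_v = 36) {
  s <- fs_sampling(surface, n_u, n_v)
  P <- evaluate_surface(surface, s$u, s$v)
  tibble::tibble(u = s$u, v = s$v, x = P[, 1], y = P[, 2], z = P[, 3])
}

#' End-to-end Fourier-surface segmentation (FS)
#'
#' [estimate_initial_ellipsoid()], [optimize_surface()] and
#' [voxelize_surface()] chained on the image grid.
#'
#' @inheritParams fixed_threshold_segment
#' @param opt An [optimizer_config()].
#' @param cfg An [objective_config()].
#' @param gradient Optional precomputed [image_gradient()].
#' @return A `binary_mask` with attributes `surface` (the fitted
#'   [fourier_surface()]) and `objective`.
#' @export
fs_segment <- function(image, init_voi, opt = optimizer_config(),
                       cfg = objective_config(), gradient = NULL) {
  check_same_grid(image, init_voi)
  if (!any(init_voi$member)) stop("initialization VOI is empty")
  e <- estimate_initial_ellipsoid(image, init_voi)
  surface <- optimize_surface(image, e, opt, cfg, gradient = gradient)
  mask <- voxelize_surface(surface, image$grid)
  attr(mask, "surface") <- surface
  attr(mask, "objective") <- attr(surface, "objective")
  mask
}
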