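#' Tumour specification for the synthetic phantom
#'
#' Shapes are kept deliberately simple and "relatively round": spheres,
#' axis-aligned ellipsoids (given as axis ratios) and "lumpy" spheres whose
#' radius is modulated by a smooth low-order random perturbation on the
#' direction sphere.
#'
#' @param centre World centre (mm).
#' @param volume_cm3 Target volume in cm^3, `> 0`.
#' @param shape `"sphere"`, `"ellipsoid"` or `"lumpy"`.
#' @param axis_ratios Relative semi-axis ratios for `"ellipsoid"`.
#' @param lumpy_amplitude Relative radius perturbation amplitude for
#'   `"lumpy"` (must keep the radius positive, so `< 1`).
#' @param lumpy_seed Seed of the lumpy perturbation.
#' @param concentration Activity concentration (arbitrary units per cm^3).
#' @return An object of class `tumour_spec`.
#' @export
tumour_spec <- function(centre, volume_cm3,
                        shape = c("sphere", "ellipsoid", "lumpy"),
                        axis_ratios = c(1, 1, 1), lumpy_amplitude = 0.15,
                        lumpy_seed = 1L, concentration = 1) {
  shape <- match.arg(shape)
  stopifnot(volume_cm3 > 0, all(axis_ratios > 0), concentration >= 0,
            lumpy_amplitude >= 0, lumpy_amplitude < 1)
  structure(list(centre = as.numeric(centre), volume_cm3 = volume_cm3,
                 shape = shape, axis_ratios = as.numeric(axis_ratios),
                 lumpy_amplitude = lumpy_amplitude,
                 lumpy_seed = as.integer(lumpy_seed),
                 concentration = concentration),
            class = "tumour_spec")
}

#' Phantom specification
#'
#' @param tumours List of [tumour_spec()] objects; must not overlap when
#'   rasterized.
#' @param grid A [voxel_grid()]; the default is 2.5 mm cubic voxels.
#' @param background Background activity concentration (same units as the
#'   tumour concentrations).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(tumours, grid = voxel_grid(c(64, 64, 64)),
                         background = 0) {
  if (inherits(tumours, "tumour_spec")) tumours <- list(tumours)
  stopifnot(background >= 0)
  structure(list(tumours = tumours, grid = grid, background = background),
            class = "phantom_spec")
}

# smooth random radius modulation on the unit sphere: a sum of low-order
# directional second-degree terms with random axes and weights
lumpy_perturbation <- function(dirs, amplitude, seed) {
  if (amplitude == 0) return(rep(0, nrow(dirs)))
  rs <- withr_seed_eval(seed, {
    axes <- matrix(stats::rnorm(18), 6, 3)
    axes <- axes / sqrt(rowSums(axes^2))
    w <- stats::runif(6, -1, 1)
    list(axes = axes, w = w)
  })
  proj <- dirs %*% t(rs$axes)                 # n x 6 direction cosines
  raw <- as.numeric((proj^2 - 1 / 3) %*% rs$w)
  if (max(abs(raw)) < .Machine$double.eps) return(rep(0, nrow(dirs)))
  amplitude * raw / max(abs(raw))
}

# evaluate-with-seed without disturbing the caller's RNG stream
withr_seed_eval <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# rasterize one tumour: pick the scale so the voxel count best matches the
# target volume (the N-th smallest normalized radial distance sets the scale)
rasterize_tumour <- function(spec, grid) {
  v_vox <- voxel_volume_cm3(grid)
  n_target <- max(1L, round(spec$volume_cm3 / v_vox))
  # nominal radius of the unit-scale shape, used only to bound the search box
  r_nom <- (3 * spec$volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  half <- r_nom * 2.5 + 3 * max(grid$spacing)
  ilo <- pmax(floor((spec$centre - half - grid$origin) / grid$spacing), 0)
  ihi <- pmin(ceiling((spec$centre + half - grid$origin) / grid$spacing),
              grid$shape - 1)
  if (any(ihi < ilo)) stop("tumour lies outside the phantom grid")
  ax <- lapply(1:3, function(a) ilo[a]:ihi[a])
  vox <- cbind(
    rep(ax[[1]], times = length(ax[[2]]) * length(ax[[3]])),
    rep(rep(ax[[2]], each = length(ax[[1]])), times = length(ax[[3]])),
    rep(ax[[3]], each = length(ax[[1]]) * length(ax[[2]]))
  )
  centres <- sweep(sweep(vox, 2, grid$spacing, "*"), 2, grid$origin, "+")
  rel <- sweep(centres, 2, spec$centre)
  if (spec$shape == "ellipsoid") {
    q <- spec$axis_ratios / prod(spec$axis_ratios)^(1 / 3)
    t <- sqrt(rowSums(sweep(rel, 2, q, "/")^2))
  } else {
    d <- sqrt(rowSums(rel^2))
    t <- d
    if (spec$shape == "lumpy") {
      dirs <- rel / pmax(d, .Machine$double.eps)
      pert <- lumpy_perturbation(dirs, spec$lumpy_amplitude, spec$lumpy_seed)
      t <- d / (1 + pert)
    }
  }
  if (n_target > length(t)) stop("tumour larger than the phantom grid")
  # exactly the n_target closest voxels; grid-symmetry ties are broken
  # deterministically by voxel order so the count (and hence the volume)
  # matches the target to within one voxel
  member_idx <- vox[order(t)[seq_len(n_target)], , drop = FALSE]
  member <- array(FALSE, grid$shape)
  member[member_idx + 1] <- TRUE
  binary_mask(member, grid)
}

#' Build a piecewise-constant activity phantom
#'
#' Rasterizes each tumour so that its voxel volume matches the target volume
#' to within about one voxel (the radial scale is solved numerically from the
#' order statistics of the voxel distances), on a uniform background.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `activity` (a [scalar_image()], activity concentration
#'   per voxel) and `truth` (class `ground_truth`: per-tumour `masks`, and a
#'   tibble `table` of true volumes (cm^3) and concentrations).
#' @export
build_phantom <- function(spec) {
  grid <- spec$grid
  vals <- array(spec$background, grid$shape)
  masks <- vector("list", length(spec$tumours))
  occupied <- array(FALSE, grid$shape)
  for (i in seq_along(spec$tumours)) {
    tm <- spec$tumours[[i]]
    m <- rasterize_tumour(tm, grid)
    if (any(m$member & occupied)) stop("tumours overlap on the voxel grid")
    occupied <- occupied | m$member
    vals[m$member] <- tm$concentration
    masks[[i]] <- m
  }
  tab <- tibble::tibble(
    tumour = seq_along(masks),
    volume_cm3 = vapply(masks, mask_volume_cm3, numeric(1)),
    concentration = vapply(spec$tumours, function(t) t$concentration,
                           numeric(1))
  )
  truth <- structure(list(masks = masks, table = tab), class = "ground_truth")
  list(activity = scalar_image(vals, grid, unit = "concentration"),
       truth = truth)
}

#' Acquisition specification for the reconstruction emulator
#'
#' The emulator stands in for projection, noise and iterative reconstruction:
#' the activity map is blurred with an isotropic Gaussian point-spread
#' function, scaled to expected counts, optionally edge-enhanced, and each
#' voxel is replaced by a Poisson draw. The edge enhancement is an
#' unsharp-mask overshoot (the difference between the expected image and a
#' copy blurred twice as wide, scaled by `edge_enhancement`) emulating the
#' high values close to object edges seen in resolution-compensated
#' reconstructions.
#'
#' @param fwhm_mm Gaussian PSF full width at half maximum (mm), `>= 0`.
#' @param count_scale Expected counts per unit activity concentration per
#'   voxel; folds in sensitivity, acquisition time and decay.
#' @param edge_enhancement Overshoot amplitude; 0 gives an AS-like image,
#'   `> 0` an ASR-like image.
#' @param n_realizations Number of Poisson noise realizations (default 30).
#' @param seed Base seed; realizations are deterministic given
#'   `(seed, realization_index)`.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(fwhm_mm = 12, count_scale = 40,
                             edge_enhancement = 0, n_realizations = 30,
                             seed = 1L) {
  stopifnot(fwhm_mm >= 0, count_scale > 0, n_realizations >= 1,
            edge_enhancement >= 0)
  structure(list(fwhm_mm = fwhm_mm, count_scale = count_scale,
                 edge_enhancement = edge_enhancement,
                 n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

# separable Gaussian blur (kernel truncated at 4 sigma, normalized to sum 1)
gaussian_blur <- function(values, grid, fwhm_mm) {
  if (fwhm_mm <= 0) return(values)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- values
  d <- dim(values)
  for (axis in 1:3) {
    sp <- grid$spacing[axis]
    r <- max(1L, ceiling(4 * sigma / sp))
    k <- stats::dnorm(seq(-r, r) * sp, sd = sigma)
    k <- k / sum(k)
    n <- d[axis]
    # dense band matrix applied to the unfolded array (n is modest)
    M <- matrix(0, n, n)
    for (j in seq(-r, r)) {
      idx <- seq_len(n)
      src <- idx + j
      ok <- src >= 1 & src <= n
      M[cbind(idx[ok], src[ok])] <- M[cbind(idx[ok], src[ok])] + k[j + r + 1]
    }
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(out, perm)
    da <- dim(a)
    a <- M %*% matrix(a, da[1], da[2] * da[3])
    dim(a) <- da
    out <- aperm(a, order(perm))
  }
  out
}

#' Expected (noise-free) reconstructed image
#'
#' @param activity A [scalar_image()] activity-concentration map.
#' @param acq An [acquisition_spec()].
#' @return A [scalar_image()] of expected counts per voxel (negative values
#'   from the overshoot are clipped to 0).
#' @export
expected_reconstruction <- function(activity, acq) {
  ex <- gaussian_blur(activity$values, activity$grid, acq$fwhm_mm) *
    acq$count_scale
  if (acq$edge_enhancement > 0) {
    broad <- gaussian_blur(ex, activity$grid, 2 * acq$fwhm_mm)
    ex <- ex + acq$edge_enhancement * (ex - broad)
    ex[ex < 0] <- 0
  }
  scalar_image(ex, activity$grid, unit = "counts")
}

#' Simulate one noisy reconstruction
#'
#' Poisson noise applied voxel-wise to [expected_reconstruction()];
#' deterministic given `(acq$seed, realization_index)` and independent of the
#' caller's RNG state.
#'
#' @inheritParams expected_reconstruction
#' @param realization_index Positive integer identifying the realization.
#' @param expected Optional precomputed [expected_reconstruction()] (saves the
#'   repeated blur when drawing many realizations).
#' @return A [scalar_image()] of counts.
#' @export
simulate_reconstruction <- function(activity, acq, realization_index = 1L,
                                    expected = NULL) {
  if (is.null(expected)) expected <- expected_reconstruction(activity, acq)
  rs <- realization_seed(acq$seed, realization_index)
  noisy <- withr_seed_eval(rs, {
    stats::rpois(length(expected$values), lambda = as.numeric(expected$values))
  })
  scalar_image(array(as.numeric(noisy), expected$grid$shape), expected$grid,
               unit = "counts")
}

# deterministic per-realization substream seed, kept within 32-bit range
realization_seed <- function(seed, realization_index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(realization_index) * 69621) %%
               2147483647)
}

#' Initialization VOI from a ground-truth mask
#'
#' The operator-drawn "rough VOI encompassing the object with a margin" is
#' emulated by dilating the true mask by `ceiling(margin / spacing)` voxels
#' per axis; the result is clipped at the grid border.
#'
#' @param truth_mask A [binary_mask()].
#' @param margin Margin in mm, `>= 0`.
#' @return A `binary_mask`.
#' @export
make_initialization_voi <- function(truth_mask, margin) {
  dilate_mask(truth_mask, margin)
}

#' Recovery-coefficient calibration phantoms
#'
#' One phantom per sphere volume: a uniform sphere of unit concentration at
#' the centre of the field of view of an elliptical water cylinder with
#' semi-axes 20 cm and 10 cm (non-radioactive background). Used with
#' [expected_reconstruction()] and [measure_rc()] to calibrate the recovery
#' curve.
#'
#' @param sphere_volumes_cm3 Positive sphere volumes (cm^3).
#' @param grid A [voxel_grid()] covering the cylinder cross-section; the
#'   default is a 2.5 mm grid slightly wider than the cylinder.
#' @param cylinder_semi_axes_mm Cylinder cross-section semi-axes (mm).
#' @return A list with one element per volume: `activity` (a
#'   [scalar_image()]), `true_mask` (a `binary_mask`) and `volume_cm3`.
#' @export
rc_phantom <- function(sphere_volumes_cm3,
                       grid = NULL,
                       cylinder_semi_axes_mm = c(200, 100)) {
  stopifnot(all(sphere_volumes_cm3 > 0))
  rmax <- (3 * max(sphere_volumes_cm3) * 1000 / (4 * pi))^(1 / 3)
  if (rmax > min(cylinder_semi_axes_mm)) {
    stop("sphere does not fit inside the calibration cylinder")
  }
  if (is.null(grid)) {
    half <- rmax + 40
    n <- ceiling(2 * half / 2.5)
    grid <- voxel_grid(c(n, n, n), spacing = 2.5,
                       origin = rep(-2.5 * (n - 1) / 2, 3))
  }
  centre <- grid$origin + (grid$shape - 1) * grid$spacing / 2
  lapply(sphere_volumes_cm3, function(vol) {
    spec <- tumour_spec(centre, vol, shape = "sphere", concentration = 1)
    mask <- rasterize_tumour(spec, grid)
    vals <- array(0, grid$shape)
    vals[mask$member] <- 1
    list(activity = scalar_image(vals, grid, unit = "concentration"),
         true_mask = mask, volume_cm3 = mask_volume_cm3(mask))
  })
}
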