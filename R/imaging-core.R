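#' Voxel grid geometry
#'
#' Axis-aligned voxel lattice shared by images and masks. Voxel `(i, j, k)`
#' (0-based) has its centre at `origin + (i * sx, j * sy, k * sz)` in world
#' millimetres. Rotated/oblique grids are not supported anywhere in the
#' package.
#'
#' @param shape Integer triple `(nx, ny, nz)`.
#' @param spacing Voxel size in mm, positive triple. Scalars are recycled.
#' @param origin World position (mm) of the centre of voxel `(0, 0, 0)`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing = c(2.5, 2.5, 2.5), origin = c(0, 0, 0)) {
  shape <- as.integer(rep_len(shape, 3L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(shape < 1L)) stop("grid shape must be positive")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be positive and finite")
  }
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing %.4g x %.4g x %.4g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @rdname voxel_grid
#' @param x,y Objects.
#' @export
grids_identical <- function(x, y) {
  identical(x$shape, y$shape) &&
    isTRUE(all.equal(x$spacing, y$spacing, tolerance = 1e-12)) &&
    isTRUE(all.equal(x$origin, y$origin, tolerance = 1e-12))
}

#' Voxel volume in cubic centimetres
#' @param grid A `voxel_grid`.
#' @return Scalar voxel volume (cm^3).
#' @export
voxel_volume_cm3 <- function(grid) prod(grid$spacing) / 1000

# world coordinates (mm) of all voxel centres, as an n x 3 matrix
grid_coordinates <- function(grid) {
  ax <- lapply(1:3, function(a) {
    grid$origin[a] + grid$spacing[a] * (seq_len(grid$shape[a]) - 1)
  })
  cbind(
    rep(ax[[1]], times = grid$shape[2] * grid$shape[3]),
    rep(rep(ax[[2]], each = grid$shape[1]), times = grid$shape[3]),
    rep(ax[[3]], each = grid$shape[1] * grid$shape[2])
  )
}

# world -> (fractional) 0-based voxel index
world_to_index <- function(grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

#' 3-D scalar image
#'
#' @param values Numeric 3-D array (counts, count rate, or activity
#'   concentration; stated in `unit`).
#' @param grid A [voxel_grid()] whose shape matches `dim(values)`. If missing,
#'   a unit 2.5 mm grid at the origin is created.
#' @param unit Free-text unit tag carried in metadata.
#' @return An object of class `scalar_image`.
#' @export
scalar_image <- function(values, grid = NULL, unit = "counts") {
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("values must be a 3-D array")
  if (is.null(grid)) grid <- voxel_grid(dim(values))
  if (!identical(as.integer(dim(values)), grid$shape)) {
    stop("value array shape must equal the grid shape")
  }
  if (any(!is.finite(values))) stop("image values must be finite")
  structure(list(grid = grid, values = values, unit = unit),
            class = "scalar_image")
}

#' @export
print.scalar_image <- function(x, ...) {
  cat(sprintf("<scalar_image> [%s] range %.4g..%.4g\n", x$unit,
              min(x$values), max(x$values)))
  print(x$grid)
  invisible(x)
}

#' Binary voxel mask (volume of interest)
#'
#' @param member Logical 3-D array.
#' @param grid A [voxel_grid()]; defaults as in [scalar_image()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(member, grid = NULL) {
  member <- as.array(member)
  if (length(dim(member)) != 3) stop("member must be a 3-D array")
  storage.mode(member) <- "logical"
  member[is.na(member)] <- FALSE
  if (is.null(grid)) grid <- voxel_grid(dim(member))
  if (!identical(as.integer(dim(member)), grid$shape)) {
    stop("member array shape must equal the grid shape")
  }
  structure(list(grid = grid, member = member), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d voxels, %.3f cm^3\n", sum(x$member),
              mask_volume_cm3(x)))
  print(x$grid)
  invisible(x)
}

#' Mask volume in cubic centimetres
#' @param mask A `binary_mask`.
#' @export
mask_volume_cm3 <- function(mask) sum(mask$member) * voxel_volume_cm3(mask$grid)

#' Trilinear interpolation at world points
#'
#' Samples a scalar image at arbitrary world positions (mm). Points outside
#' the voxel-centre hull return 0, matching the behaviour of count images
#' whose background tends to zero.
#'
#' @param image A [scalar_image()].
#' @param points Numeric vector of length 3 or an `n x 3` matrix of world
#'   coordinates (mm).
#' @return Numeric vector of sampled values.
#' @export
trilinear_sample <- function(image, points) {
  pts <- matrix(as.numeric(points), ncol = 3)
  cpp_trilinear(as.numeric(image$values), image$grid$shape,
                image$grid$spacing, image$grid$origin, pts)
}

#' Image gradient by 3x3x3 difference kernels
#'
#' Each component is a Prewitt-style antisymmetric difference: the central
#' difference along the target axis averaged over the 3x3 transverse
#' neighbourhood, scaled so that a ramp of unit slope per mm yields component
#' 1 (units: image value per mm). Borders are handled by edge replication.
#'
#' @param image A [scalar_image()] with at least 3 voxels per axis.
#' @return A list of class `vector_field` with components `x`, `y`, `z`
#'   (arrays on the image grid) and the `grid`.
#' @export
image_gradient <- function(image) {
  d <- dim(image$values)
  if (any(d < 3)) stop("image must have at least 3 voxels per axis")
  pad <- pad_replicate(image$values)
  comp <- vector("list", 3)
  for (axis in 1:3) {
    acc <- 0
    tr <- setdiff(1:3, axis)
    for (o1 in -1:1) for (o2 in -1:1) {
      offp <- offm <- c(0L, 0L, 0L)
      offp[axis] <- 1L; offm[axis] <- -1L
      offp[tr] <- offm[tr] <- c(o1, o2)
      acc <- acc + shifted_window(pad, d, offp) - shifted_window(pad, d, offm)
    }
    comp[[axis]] <- acc / (18 * image$grid$spacing[axis])
  }
  structure(list(grid = image$grid, x = comp[[1]], y = comp[[2]],
                 z = comp[[3]]), class = "vector_field")
}

# pad a 3-D array by one voxel on each side with edge replication
pad_replicate <- function(a) {
  d <- dim(a)
  ix <- c(1, seq_len(d[1]), d[1])
  iy <- c(1, seq_len(d[2]), d[2])
  iz <- c(1, seq_len(d[3]), d[3])
  a[ix, iy, iz, drop = FALSE]
}

# window of a padded array shifted by off (relative to the unpadded frame)
shifted_window <- function(pad, d, off) {
  pad[1 + off[1] + seq_len(d[1]), 1 + off[2] + seq_len(d[2]),
      1 + off[3] + seq_len(d[3]), drop = FALSE]
}

# separable box dilation/erosion with per-axis half-widths k (voxels);
# outside the grid is treated as background
box_morph <- function(member, k, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(member)
  out <- member
  if (op == "erode") out <- !out
  for (axis in 1:3) {
    if (k[axis] < 1L) next
    acc <- out
    for (s in seq_len(k[axis])) {
      acc <- acc | shift_logical(out, axis, s, d) |
        shift_logical(out, axis, -s, d)
    }
    out <- acc
  }
  if (op == "erode") out <- !out
  out
}

# shift a logical array along one axis, filling with FALSE
shift_logical <- function(a, axis, s, d) {
  out <- array(FALSE, d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- if (s > 0) (1 + s):n else 1:(n + s)
  idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Morphological closing with a 3x3x3 cube
#'
#' Dilation followed by erosion with a full 3x3x3 (26-neighbourhood)
#' structuring element. Voxels outside the grid are treated as background.
#'
#' @param mask A [binary_mask()].
#' @return A `binary_mask` on the same grid.
#' @export
binary_closing <- function(mask) {
  dil <- box_morph(mask$member, c(1L, 1L, 1L), "dilate")
  ero <- box_morph(dil, c(1L, 1L, 1L), "erode")
  binary_mask(ero, mask$grid)
}

#' Isotropic mask dilation by a metric margin
#'
#' Dilates with a box structuring element whose per-axis half-width is
#' `ceiling(margin / spacing)` voxels; the result is clipped at the grid
#' border. Used to derive initialization VOIs from ground-truth masks.
#'
#' @param mask A [binary_mask()].
#' @param margin Margin in mm, `>= 0`.
#' @return A `binary_mask` on the same grid.
#' @export
dilate_mask <- function(mask, margin) {
  stopifnot(margin >= 0)
  k <- as.integer(ceiling(margin / mask$grid$spacing - 1e-9))
  binary_mask(box_morph(mask$member, pmax(k, 0L), "dilate"), mask$grid)
}

#' Fill cavities and drop disconnected islands
#'
#' Background is defined as the set of non-member voxels 6-connected to the
#' grid border; the result is the 6-connected component of the complement of
#' that background which contains the seed. Cavities enclosed by the mask are
#' filled, and member islands not connected to the seed are removed.
#'
#' @param mask A [binary_mask()].
#' @param seed World point (mm) assumed to lie inside the object.
#' @return A `binary_mask`; if the seed voxel turns out to be background the
#'   mask is empty and carries attribute `degenerate = TRUE`.
#' @export
solidify <- function(mask, seed) {
  g <- mask$grid
  idx <- round(world_to_index(g, seed))
  if (any(idx < 0) || any(idx >= matrix(g$shape, 1))) {
    stop("seed must lie inside the grid")
  }
  lin <- idx[1] + g$shape[1] * (idx[2] + g$shape[2] * idx[3])
  bg <- cpp_flood_background(as.logical(mask$member), g$shape)
  candidate <- !bg
  comp <- cpp_component_from_seed(candidate, g$shape, as.integer(lin))
  out <- binary_mask(array(comp, g$shape), g)
  if (!any(out$member)) {
    attr(out, "degenerate") <- TRUE
    warning("seed voxel is connected to the background; returning empty mask")
  }
  out
}

#' Largest 6-connected component of a mask
#' @param mask A [binary_mask()].
#' @return A `binary_mask` retaining only the largest component.
#' @export
largest_component <- function(mask) {
  lab <- cpp_label_components(as.logical(mask$member), mask$grid$shape)
  if (all(lab == 0L)) return(mask)
  counts <- tabulate(lab)
  keep <- which.max(counts)
  binary_mask(array(lab == keep, mask$grid$shape), mask$grid)
}
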