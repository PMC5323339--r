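#' Fixed-threshold segmentation (FT)
#'
#' Classic fixed relative threshold: the threshold is set to `fraction`
#' (default 42%) of the maximum voxel value inside the initialization VOI, and
#' every VOI voxel with value greater than or equal to the threshold becomes
#' object. No connectivity repair is applied, so spurious non-connected
#' islands are possible at high noise -- that is a property of the method, not
#' a defect of the implementation.
#'
#' @param image A [scalar_image()].
#' @param init_voi A [binary_mask()] on the same grid, nonempty.
#' @param fraction Relative threshold in (0, 1); default 0.42.
#' @return A list of class `threshold_result` with elements `threshold`,
#'   `mask` (a `binary_mask`) and `method = "FT"`.
#' @export
fixed_threshold_segment <- function(image, init_voi, fraction = 0.42) {
  check_same_grid(image, init_voi)
  if (!any(init_voi$member)) stop("initialization VOI is empty")
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  mx <- max(image$values[init_voi$member])
  if (mx <= 0) stop("no object signal: maximum value in the VOI is not positive")
  thr <- fraction * mx
  member <- init_voi$member & (image$values >= thr)
  structure(list(threshold = thr, mask = binary_mask(member, image$grid),
                 method = "FT"),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> method %s, threshold %.6g, %d voxels (%.3f cm^3)\n",
              x$method, x$threshold, sum(x$mask$member),
              mask_volume_cm3(x$mask)))
  invisible(x)
}

#' Otsu threshold on continuous values
#'
#' Modified Otsu method for floating-point data: instead of binning a
#' grey-level histogram, every unique value is regarded as a candidate
#' threshold. A candidate `t` assigns values `<= t` to the background class
#' and values `> t` to the object class; the candidate maximizing the
#' between-class variance `w0 * w1 * (mu0 - mu1)^2` is returned. Any real
#' threshold strictly between two consecutive unique values yields the same
#' classification, so returning the unique value itself loses nothing. Ties
#' are broken towards the lowest candidate (the larger object).
#'
#' @param values Numeric vector with at least 2 unique values.
#' @return The selected threshold (one of the unique values).
#' @export
otsu_threshold <- function(values) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite")
  u <- sort(unique(values))
  if (length(u) < 2) {
    stop("degenerate histogram: need at least 2 unique values")
  }
  vs <- sort(values)
  n <- length(vs)
  # class split after the last element <= u[i]; cumulative sums over sorted data
  cnt <- findInterval(u, vs)            # size of class 0 for candidate u[i]
  csum <- cumsum(vs)
  total <- csum[n]
  s0 <- csum[cnt]
  w0 <- cnt / n
  w1 <- 1 - w0
  mu0 <- s0 / cnt
  mu1 <- ifelse(cnt < n, (total - s0) / (n - cnt), 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[length(u)] <- 0                   # all-in-one-class split carries no variance
  u[which.max(bcv)]                     # which.max takes the first (lowest) tie
}

#' Otsu segmentation within an initialization VOI (OM)
#'
#' Applies [otsu_threshold()] to the voxel values inside the initialization
#' VOI and keeps the high (object) class. Like FT, no connectivity repair is
#' applied.
#'
#' @inheritParams fixed_threshold_segment
#' @return A `threshold_result` with `method = "OM"`.
#' @export
otsu_segment <- function(image, init_voi) {
  check_same_grid(image, init_voi)
  if (!any(init_voi$member)) stop("initialization VOI is empty")
  thr <- otsu_threshold(image$values[init_voi$member])
  member <- init_voi$member & (image$values > thr)
  structure(list(threshold = thr, mask = binary_mask(member, image$grid),
                 method = "OM"),
            class = "threshold_result")
}

check_same_grid <- function(image, mask) {
  if (!grids_identical(image$grid, mask$grid)) {
    stop("image and mask must share the same voxel grid")
  }
  invisible(TRUE)
}
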