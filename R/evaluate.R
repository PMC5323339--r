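#' Relative error statistics over noise realizations
#'
#' For per-realization estimates `V_i` against a reference `V_ref`:
#' the relative mean error `E = mean(V_i) / V_ref - 1` (trueness), the
#' relative standard deviation `rSD = sd(V_i) / V_ref` (precision, with the
#' `N - 1` denominator) and the relative root-mean-square error
#' `rRMSE = sqrt(mean((V_i - V_ref)^2)) / V_ref` (accuracy, with the `N`
#' denominator). The three satisfy
#' `rRMSE^2 = E^2 + rSD^2 * (N - 1) / N` identically.
#'
#' @param estimates Numeric vector of per-realization estimates (nonempty).
#' @param reference Reference value, `> 0`.
#' @return A list of class `error_stats` with `mean_error`, `rsd` (`NA` with
#'   `rsd_defined = FALSE` when `N = 1`), `rrmse`, `n`, `reference`,
#'   `estimates`.
#' @export
error_stats <- function(estimates, reference) {
  estimates <- as.numeric(estimates)
  if (length(estimates) == 0) stop("estimates must be nonempty")
  stopifnot(reference > 0)
  n <- length(estimates)
  e_bar <- mean(estimates) / reference - 1
  rsd <- if (n >= 2) stats::sd(estimates) / reference else NA_real_
  rrmse <- sqrt(mean((estimates - reference)^2)) / reference
  structure(list(mean_error = e_bar, rsd = rsd, rrmse = rrmse, n = n,
                 rsd_defined = n >= 2, reference = reference,
                 estimates = estimates),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf("<error_stats> N = %d: E = %+.1f%% +/- %.1f%% (rRMSE %.1f%%)\n",
              x$n, 100 * x$mean_error, 100 * x$rsd, 100 * x$rrmse))
  invisible(x)
}

#' @export
tidy.error_stats <- function(x, ...) {
  tibble::tibble(mean_error = x$mean_error, rsd = x$rsd, rrmse = x$rrmse,
                 n = x$n, reference = x$reference)
}

#' Dice similarity coefficient across voxel grids
#'
#' Treats the member voxels of each mask as rectangular cuboids and computes
#' `DSC = 2 mu(S1 int S2) / (mu(S1) + mu(S2))` from the exact summed
#' intersection volume of the cuboids, so the two masks may live on grids
#' with different spacing and origin (both axis-aligned). The overlap is
#' computed analytically by contracting the second mask through the three
#' per-axis interval-overlap matrices; on identical grids this reduces
#' exactly to the classical voxel-count Dice.
#'
#' @param mask_a,mask_b [binary_mask()]s on axis-aligned grids.
#' @return A list of class `dsc_result` with `dsc`, `overlap_cm3`,
#'   `volume_a_cm3`, `volume_b_cm3` and `degenerate` (`TRUE` when both masks
#'   are empty, in which case `dsc = 0`).
#' @export
dice_cross_grid <- function(mask_a, mask_b) {
  va <- mask_volume_cm3(mask_a)
  vb <- mask_volume_cm3(mask_b)
  if (va == 0 && vb == 0) {
    return(structure(list(dsc = 0, overlap_cm3 = 0, volume_a_cm3 = 0,
                          volume_b_cm3 = 0, degenerate = TRUE),
                     class = "dsc_result"))
  }
  if (grids_identical(mask_a$grid, mask_b$grid)) {
    overlap <- sum(mask_a$member & mask_b$member) *
      voxel_volume_cm3(mask_a$grid)
  } else {
    ov <- lapply(1:3, function(ax) {
      axis_overlap_matrix(mask_a$grid, mask_b$grid, ax)
    })
    # contract B through the per-axis overlap matrices onto A's lattice
    arr <- array(as.numeric(mask_b$member), mask_b$grid$shape)
    for (ax in 1:3) {
      perm <- c(ax, setdiff(1:3, ax))
      a <- aperm(arr, perm)
      da <- dim(a)
      a <- ov[[ax]] %*% matrix(a, da[1], da[2] * da[3])
      dim(a) <- c(nrow(ov[[ax]]), da[2], da[3])
      arr <- aperm(a, order(perm))
    }
    overlap <- sum(arr[mask_a$member]) / 1000   # mm^3 -> cm^3
  }
  structure(list(dsc = 2 * overlap / (va + vb), overlap_cm3 = overlap,
                 volume_a_cm3 = va, volume_b_cm3 = vb, degenerate = FALSE),
            class = "dsc_result")
}

# interval-overlap lengths (mm) between the voxel extents of two grids along
# one axis: entry (i, j) = |[a_i, a_i + sa] int [b_j, b_j + sb]|
axis_overlap_matrix <- function(ga, gb, axis) {
  sa <- ga$spacing[axis]; sb <- gb$spacing[axis]
  a0 <- ga$origin[axis] - sa / 2 + sa * (seq_len(ga$shape[axis]) - 1)
  b0 <- gb$origin[axis] - sb / 2 + sb * (seq_len(gb$shape[axis]) - 1)
  hi <- outer(a0 + sa, b0 + sb, pmin)
  lo <- outer(a0, b0, pmax)
  m <- hi - lo
  m[m < 0] <- 0
  m
}

#' @export
print.dsc_result <- function(x, ...) {
  cat(sprintf("<dsc_result> DSC = %.4f (overlap %.3f cm^3; volumes %.3f / %.3f cm^3)%s\n",
              x$dsc, x$overlap_cm3, x$volume_a_cm3, x$volume_b_cm3,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
tidy.dsc_result <- function(x, ...) {
  tibble::tibble(dsc = x$dsc, overlap_cm3 = x$overlap_cm3,
                 volume_a_cm3 = x$volume_a_cm3, volume_b_cm3 = x$volume_b_cm3,
                 degenerate = x$degenerate)
}

#' Percentile summary of Dice coefficients
#'
#' The 50th (10th, 90th) percentiles with the linear-interpolation convention
#' (R quantile type 7).
#'
#' @param dscs Nonempty numeric vector.
#' @return Named numeric vector `p50`, `p10`, `p90`.
#' @export
summarize_dsc <- function(dscs) {
  dscs <- as.numeric(dscs)
  if (length(dscs) == 0) stop("empty DSC list")
  q <- stats::quantile(dscs, c(0.5, 0.1, 0.9), type = 7, names = FALSE)
  c(p50 = q[1], p10 = q[2], p90 = q[3])
}
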