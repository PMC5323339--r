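#' System calibration
#'
#' @param sensitivity Count rate per unit activity (the system sensitivity,
#'   measured in air), `> 0`.
#' @param v_vox Voxel volume, `> 0` (units consistent with the concentration
#'   to be reported; cm^3 throughout the package).
#' @return An object of class `calibration`.
#' @export
calibration <- function(sensitivity, v_vox) {
  stopifnot(sensitivity > 0, v_vox > 0)
  structure(list(sensitivity = sensitivity, v_vox = v_vox),
            class = "calibration")
}

#' Calibration implied by a synthetic acquisition
#'
#' In the simulator, `count_scale` is the expected counts per unit activity
#' concentration per voxel, i.e. `sensitivity * v_vox`; this helper returns
#' the matching [calibration()] so that synthetic quantification is
#' self-consistent.
#'
#' @param acq An [acquisition_spec()].
#' @param grid The reconstruction [voxel_grid()].
#' @export
calibration_from_acquisition <- function(acq, grid) {
  v <- voxel_volume_cm3(grid)
  calibration(sensitivity = acq$count_scale / v, v_vox = v)
}

#' System sensitivity from a planar acquisition
#'
#' For real data the sensitivity is measured from a planar image of a source
#' of known activity: total counts divided by (activity x duration).
#'
#' @param planar Numeric matrix or array of planar counts.
#' @param activity Source activity.
#' @param duration Acquisition duration (same time unit as the count rate).
#' @return Sensitivity (count rate per unit activity).
#' @export
sensitivity_from_planar <- function(planar, activity, duration = 1) {
  stopifnot(activity > 0, duration > 0)
  sum(planar) / (activity * duration)
}

#' Measure a recovery coefficient
#'
#' Ratio between the activity concentration estimated from the image inside
#' the true VOI (mean counts per voxel divided by `sensitivity * v_vox`) and
#' the true concentration.
#'
#' @param recon A reconstructed [scalar_image()] (counts or count rate).
#' @param true_voi The true sphere [binary_mask()].
#' @param true_concentration True activity concentration, `> 0`.
#' @param cal A [calibration()].
#' @return Scalar recovery coefficient.
#' @export
measure_rc <- function(recon, true_voi, true_concentration, cal) {
  check_same_grid(recon, true_voi)
  if (!any(true_voi$member)) stop("true VOI is empty")
  stopifnot(true_concentration > 0)
  n_bar <- mean(recon$values[true_voi$member])
  (n_bar / (cal$sensitivity * cal$v_vox)) / true_concentration
}

#' Fit the recovery curve R(V) = 1 / (1 + (a/V)^b)
#'
#' Unweighted least squares in `(a, b)` with positivity enforced by a log
#' parameterization. By construction the fitted curve is strictly increasing
#' in volume, lies in (0, 1) and satisfies `R(a) = 0.5`.
#'
#' @param volumes Sphere volumes (cm^3), at least 3.
#' @param rcs Measured recovery coefficients; at least two must lie strictly
#'   inside (0, 1).
#' @return An object of class `rc_curve` with elements `a`, `b`,
#'   `residuals`, `fitted`, `data`.
#' @export
fit_rc_curve <- function(volumes, rcs) {
  volumes <- as.numeric(volumes)
  rcs <- as.numeric(rcs)
  stopifnot(length(volumes) == length(rcs), length(volumes) >= 3,
            all(volumes > 0))
  if (sum(rcs > 0 & rcs < 1) < 2) {
    stop("degenerate recovery data: need at least two RCs strictly in (0, 1)")
  }
  model <- function(p, V) 1 / (1 + (exp(p[1]) / V)^exp(p[2]))
  sse <- function(p) sum((rcs - model(p, volumes))^2)
  # start: a near the half-recovery volume, b = 1
  ord <- order(volumes)
  a0 <- stats::approx(rcs[ord], volumes[ord], xout = 0.5, ties = mean,
                      rule = 2)$y
  if (!is.finite(a0) || a0 <= 0) a0 <- stats::median(volumes)
  p0 <- c(log(a0), 0)
  fit <- stats::optim(p0, sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  fit <- stats::optim(fit$par, sse, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  if (!is.finite(fit$value)) stop("recovery-curve fit did not converge")
  a <- exp(fit$par[1]); b <- exp(fit$par[2])
  fitted <- model(fit$par, volumes)
  structure(list(a = a, b = b, fitted = fitted, residuals = rcs - fitted,
                 data = tibble::tibble(volume_cm3 = volumes, rc = rcs)),
            class = "rc_curve")
}

#' @export
print.rc_curve <- function(x, ...) {
  cat(sprintf("<rc_curve> R(V) = 1 / (1 + (a/V)^b), a = %.4g cm^3, b = %.4g\n",
              x$a, x$b))
  cat(sprintf("  %d calibration points, RSS = %.3g\n", nrow(x$data),
              sum(x$residuals^2)))
  invisible(x)
}

#' @export
predict.rc_curve <- function(object, volumes, ...) {
  1 / (1 + (object$a / volumes)^object$b)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rc_curve <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @export
glance.rc_curve <- function(x, ...) {
  tibble::tibble(n = nrow(x$data), rss = sum(x$residuals^2),
                 half_recovery_volume_cm3 = x$a)
}

#' Read and write recovery-curve parameters as JSON, and calibration tables
#' as CSV
#'
#' @param rc An `rc_curve`.
#' @param path File path.
#' @return `read_rc_json()` returns a bare `rc_curve` (parameters only).
#' @export
write_rc_json <- function(rc, path) {
  jsonlite::write_json(list(a = rc$a, b = rc$b), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_rc_json
#' @export
read_rc_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(a = obj$a, b = obj$b, fitted = numeric(0),
                 residuals = numeric(0),
                 data = tibble::tibble(volume_cm3 = numeric(0),
                                       rc = numeric(0))),
            class = "rc_curve")
}

#' @rdname write_rc_json
#' @export
write_rc_table <- function(rc, path) {
  utils::write.csv(rc$data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rc_json
#' @export
read_rc_table <- function(path) {
  df <- utils::read.csv(path)
  fit_rc_curve(df$volume_cm3, df$rc)
}

#' Estimate the activity concentration in a VOI
#'
#' `C = n / (R(V_tum) * sensitivity * v_vox)` where `n` is the mean
#' count(-rate) per voxel inside the VOI and `V_tum` the VOI volume. The
#' recovery is evaluated at the estimated (not true) volume, so segmentation
#' volume errors propagate into the concentration exactly as they do in
#' practice.
#'
#' @param image Reconstructed [scalar_image()].
#' @param voi Tumour [binary_mask()] (nonempty, same grid).
#' @param rc An [fit_rc_curve()] result, or `NULL` for no partial-volume
#'   correction (`R = 1`).
#' @param cal A [calibration()].
#' @return A list of class `concentration_estimate` with `C`, `n`,
#'   `volume_cm3` and `rc_used`.
#' @export
estimate_concentration <- function(image, voi, rc, cal) {
  check_same_grid(image, voi)
  if (!any(voi$member)) stop("VOI is empty")
  v_tum <- mask_volume_cm3(voi)
  n_bar <- mean(image$values[voi$member])
  r <- if (is.null(rc)) 1 else predict(rc, v_tum)
  if (!is.finite(r) || r <= 0) stop("recovery coefficient is not positive")
  structure(list(C = n_bar / (r * cal$sensitivity * cal$v_vox), n = n_bar,
                 volume_cm3 = v_tum, rc_used = r),
            class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("<concentration_estimate> C = %.5g (n = %.4g, V = %.3f cm^3, R = %.3f)\n",
              x$C, x$n, x$volume_cm3, x$rc_used))
  invisible(x)
}

#' @export
tidy.concentration_estimate <- function(x, ...) {
  tibble::tibble(concentration = x$C, mean_counts_per_voxel = x$n,
                 volume_cm3 = x$volume_cm3, rc_used = x$rc_used)
}

#' Apply a VOI/image combination
#'
#' The study design crosses the image used for delineation with the image the
#' VOI is applied to (e.g. `AS/ASR`: segment on the AS image, measure on the
#' ASR image).
#'
#' @param masks Named list of segmentation [binary_mask()]s keyed by image tag.
#' @param images Named list of [scalar_image()]s keyed by image tag.
#' @param combo Character pair `c(source, target)` or a string
#'   `"source/target"`.
#' @param rc,cal Passed to [estimate_concentration()].
#' @return A `concentration_estimate`.
#' @export
apply_voi_combination <- function(masks, images, combo, rc, cal) {
  if (is.character(combo) && length(combo) == 1) {
    combo <- strsplit(combo, "/", fixed = TRUE)[[1]]
  }
  stopifnot(length(combo) == 2)
  if (!combo[1] %in% names(masks)) stop("unknown VOI source tag: ", combo[1])
  if (!combo[2] %in% names(images)) stop("unknown image target tag: ", combo[2])
  estimate_concentration(images[[combo[2]]], masks[[combo[1]]], rc, cal)
}
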