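#' Plot a recovery curve fit
#'
#' Calibration points and the fitted `R(V) = 1 / (1 + (a/V)^b)` on a log
#' volume axis.
#'
#' @param object An `rc_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rc_curve <- function(object, ...) {
  vgrid <- exp(seq(log(min(object$data$volume_cm3)),
                   log(max(object$data$volume_cm3)), length.out = 200))
  curve_df <- data.frame(volume_cm3 = vgrid,
                         rc = predict(object, vgrid))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$volume_cm3,
                                            y = .data$rc)) +
    ggplot2::geom_line(data = curve_df, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "volume (cm³)", y = "recovery coefficient",
                  title = sprintf("R(V) = 1/(1+(a/V)^b), a = %.3g cm³, b = %.3g",
                                  object$a, object$b)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an axial slice of an image with optional mask contours
#'
#' @param image A [scalar_image()].
#' @param k 0-based z-slice index (default: middle slice).
#' @param masks Optional named list of [binary_mask()]s on the same grid,
#'   drawn as filled contours.
#' @return A ggplot object.
#' @export
plot_slice <- function(image, k = NULL, masks = NULL) {
  g <- image$grid
  if (is.null(k)) k <- (g$shape[3] - 1) %/% 2
  stopifnot(k >= 0, k < g$shape[3])
  xs <- g$origin[1] + g$spacing[1] * (seq_len(g$shape[1]) - 1)
  ys <- g$origin[2] + g$spacing[2] * (seq_len(g$shape[2]) - 1)
  df <- expand.grid(x = xs, y = ys)
  df$value <- as.vector(image$values[, , k + 1])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = image$unit) +
    ggplot2::theme_minimal()
  if (!is.null(masks)) {
    for (nm in names(masks)) {
      m <- masks[[nm]]
      md <- df
      md$m <- as.numeric(as.vector(m$member[, , k + 1]))
      if (any(md$m > 0)) {
        p <- p + ggplot2::geom_contour(data = md,
                                       ggplot2::aes(z = .data$m,
                                                    colour = !!nm),
                                       breaks = 0.5, linewidth = 0.6)
      }
    }
    p <- p + ggplot2::labs(colour = "mask")
  }
  p
}

#' Plot study summary error bars
#'
#' Mean relative error with rSD bars per tumour, faceted by preset and image
#' or combination, coloured by method; one panel set per quantity.
#'
#' @param study A `spect_study` from [run_study()].
#' @param quantity `"volume"` or `"concentration"`.
#' @return A ggplot object.
#' @export
plot_study_errors <- function(study, quantity = c("volume", "concentration")) {
  quantity <- match.arg(quantity)
  df <- study$summary[study$summary$quantity == quantity, ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(signif(.data$reference, 3)),
                                   y = 100 * .data$mean_error,
                                   colour = .data$method)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = 100 * (.data$mean_error - .data$rsd),
                                        ymax = 100 * (.data$mean_error + .data$rsd)),
                           width = 0.2,
                           position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_grid(preset ~ image) +
    ggplot2::labs(x = sprintf("reference %s", quantity),
                  y = "relative error (%)") +
    ggplot2::theme_bw()
}

#' @importFrom rlang .data
#' @keywords internal
NULL
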