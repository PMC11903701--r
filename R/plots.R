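#' Plot a depth map with its wound mask outline
#'
#' Raster view of a depth map (meters) with the mask boundary overlaid,
#' image row 1 at the top.
#'
#' @param depth H x W depth matrix (or a `phantom_scene`).
#' @param mask Optional H x W mask; taken from the scene when given one.
#' @return A ggplot object.
#' @export
plot_depth_map <- function(depth, mask = NULL) {
  if (inherits(depth, "phantom_scene")) {
    mask <- depth$mask
    depth <- depth$depth
  }
  H <- nrow(depth); W <- ncol(depth)
  df <- tibble::tibble(
    u = rep(seq_len(W) - 1, each = H),
    v = rep(seq_len(H) - 1, times = W),
    depth = as.vector(depth)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v, fill = .data$depth)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = "depth (m)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "u (px)", y = "v (px)")
  if (!is.null(mask) && any(mask)) {
    bnd <- trace_boundary(mask)
    p <- p + ggplot2::geom_path(
      data = tibble::tibble(u = bnd[, "col"] - 1, v = bnd[, "row"] - 1),
      ggplot2::aes(x = .data$u, y = .data$v), inherit.aes = FALSE,
      colour = "red", linewidth = 0.4)
  }
  p
}

#' @exportS3Method
autoplot.phantom_scene <- function(object, ...) plot_depth_map(object)

#' @exportS3Method
autoplot.cohort_summary <- function(object, ...) {
  stopifnot(all(c("curvature_mean", "ratio_3d_2d_mean") %in% names(object)))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$curvature_mean,
                                       y = .data$ratio_3d_2d_mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$ratio_3d_2d_mean - .data$ratio_3d_2d_sd,
      ymax = .data$ratio_3d_2d_mean + .data$ratio_3d_2d_sd), width = 0.003) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$location),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "cross-section curvature (1/cm, diameter convention)",
                  y = "3D / 2D area ratio")
}

#' @exportS3Method
autoplot.area_fit <- function(object, ...) {
  df <- object$records
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[object$predictor]],
                                   y = .data[[object$response]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      title = sprintf("y = %.4g x + %.4g,  R^2 = %.4g",
                      object$slope, object$intercept, object$r_squared),
      x = object$predictor, y = object$response)
}
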