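#' Plot a displacement field
#'
#' Arrow plot of the sampled displacement vectors.
#'
#' @param object A [displacement_field()].
#' @param arrow_scale Multiplier applied to the arrows for visibility.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.displacement_field <- function(object, arrow_scale = 1, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + arrow_scale * .data$ux,
                   yend = .data$y + arrow_scale * .data$uy,
                   colour = sqrt(.data$ux^2 + .data$uy^2)),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.03, "npc"))
    ) +
    ggplot2::scale_colour_viridis_c(name = "|u|") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0("x (", field_unit(object), ")"),
                  y = paste0("y (", field_unit(object), ")"))
}

#' @export
plot.displacement_field <- function(x, ...) print(autoplot(x, ...))

#' Plot a reconstructed traction field
#'
#' Raster of the traction magnitude on the node grid.
#'
#' @param object A `tfm_fit` (with grid) or `tfm_evidence`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tfm_fit <- function(object, ...) {
  df <- tidy(object)
  if (all(is.na(df$x))) {
    stop("Fit carries no node grid; nothing to plot.", call. = FALSE)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|t| (Pa)") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$method)
}

#' @export
autoplot.tfm_evidence <- function(object, ...) {
  surf <- object$surface
  if (length(unique(surf$beta)) == 1) {
    ggplot2::ggplot(surf, ggplot2::aes(x = .data$alpha,
                                       y = .data$log_evidence)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = object$alpha, linetype = 2) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "alpha", y = "log evidence",
                    title = object$method)
  } else {
    ggplot2::ggplot(surf, ggplot2::aes(x = .data$alpha, y = .data$beta,
                                       fill = .data$log_evidence)) +
      ggplot2::geom_raster() +
      ggplot2::annotate("point", x = object$alpha, y = object$beta,
                        shape = 4, colour = "white") +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::scale_fill_viridis_c(name = "log evidence") +
      ggplot2::labs(x = "alpha", y = "beta", title = object$method)
  }
}

#' @export
plot.tfm_evidence <- function(x, ...) print(autoplot(x, ...))

#' @export
autoplot.tfm_lcurve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  corner <- attr(object, "corner_lambda")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$residual_norm,
                                        y = .data$solution_norm)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "residual norm", y = "solution norm")
  if (!is.na(corner)) {
    cp <- df[which.min(abs(df$lambda - corner)), ]
    p <- p + ggplot2::geom_point(data = cp, colour = "red", size = 2)
  }
  p
}

#' @export
plot.tfm_lcurve <- function(x, ...) print(autoplot(x, ...))

#' @importFrom rlang .data
NULL
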