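#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the energy trace of an evolution
#'
#' @param x A `levelset_evolution` object.
#' @param ... Unused.
#' @return The energy trace tibble (one row per checkpoint).
#' @method tidy levelset_evolution
#' @export
tidy.levelset_evolution <- function(x, ...) {
  x$energies
}

#' One-row summary of an evolution
#'
#' @param x A `levelset_evolution` object.
#' @param ... Unused.
#' @return Tibble with model, iteration count, convergence flag, foreground
#'   area, and the final energy components.
#' @method glance levelset_evolution
#' @export
glance.levelset_evolution <- function(x, ...) {
  fin <- x$energies[nrow(x$energies), ]
  tibble::tibble(
    model = x$model,
    iterations = x$iterations,
    converged = x$converged,
    foreground_pixels = sum(x$mask),
    total = fin$total,
    global = fin$global,
    local_printed = fin$local_printed,
    local_residual = fin$local_residual,
    length = fin$length
  )
}

#' Plot the energy trace of an evolution
#'
#' One line per energy component against iteration.
#'
#' @param object A `levelset_evolution` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.levelset_evolution <- function(object, ...) {
  e <- object$energies
  long <- tibble::tibble(
    iteration = rep(e$iteration, 4L),
    component = rep(c("global", "local_printed", "local_residual", "length"),
                    each = nrow(e)),
    value = c(e$global, e$local_printed, e$local_residual, e$length)
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$iteration, y = .data$value,
                               color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "energy",
                  title = sprintf("%s model energy trace", object$model)) +
    ggplot2::theme_minimal()
}

raster_df <- function(m, value = "value") {
  out <- tibble::tibble(
    row = rep(0:(nrow(m) - 1), ncol(m)),
    col = rep(0:(ncol(m) - 1), each = nrow(m))
  )
  out[[value]] <- as.vector(m)
  out
}

#' Plot a segmentation over its image
#'
#' Grayscale image with the segmented contour; optionally the ground-truth
#' contour for comparison.
#'
#' @param result A `levelset_evolution` object.
#' @param image The segmented image matrix.
#' @param truth Optional ground-truth logical mask.
#' @return A ggplot.
#' @export
plot_segmentation <- function(result, image, truth = NULL) {
  stopifnot(inherits(result, "levelset_evolution"))
  df <- raster_df(image, "intensity")
  df$phi <- as.vector(result$phi)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$phi), breaks = 0,
                          color = "green", linewidth = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(truth)) {
    df$truth <- as.vector(truth * 1)
    p <- p + ggplot2::geom_contour(ggplot2::aes(z = .data$truth),
                                   breaks = 0.5, color = "red",
                                   linewidth = 0.4, data = df)
  }
  p
}

#' Plot a phantom and its ground truth
#'
#' @param object A `phantom` object from [make_phantom()].
#' @param ... Unused.
#' @return A ggplot of the corrupted image with the true contour overlaid.
#' @export
autoplot.phantom <- function(object, ...) {
  df <- raster_df(object$image, "intensity")
  df$truth <- as.vector(object$mask * 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$truth), breaks = 0.5,
                          color = "red", linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$spec$kind) +
    ggplot2::theme_void()
}

#' @importFrom rlang .data
NULL
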