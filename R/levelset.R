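#' Regularized Heaviside function
#'
#' Smooth arctan approximation of the unit step,
#' \eqn{H_\epsilon(z) = \tfrac12 [1 + \tfrac{2}{\pi}\arctan(z/\epsilon)]}.
#' Region integrals over the interior/exterior of the contour are written
#' with this function applied to the level-set field.
#'
#' @param z Scalar or numeric matrix.
#' @param eps Positive regularization width.
#' @return Values strictly in (0, 1), elementwise on fields.
#' @examples
#' heaviside_eps(0, 1)          # 0.5
#' heaviside_eps(1, 1)          # 0.75
#' @seealso [delta_eps()]
#' @export
heaviside_eps <- function(z, eps) {
  check_eps(eps)
  0.5 * (1 + (2 / pi) * atan(z / eps))
}

#' Regularized delta function
#'
#' Derivative of [heaviside_eps()]:
#' \eqn{\delta_\epsilon(z) = \frac{1}{\pi}\,\frac{\epsilon}{\epsilon^2+z^2}}.
#' Strictly positive with unit integral; even in `z`.
#'
#' @inheritParams heaviside_eps
#' @return Strictly positive values, elementwise on fields.
#' @examples
#' delta_eps(0, 1)  # 1/pi
#' @export
delta_eps <- function(z, eps) {
  check_eps(eps)
  (1 / pi) * eps / (eps^2 + z^2)
}

check_eps <- function(eps) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0) {
    stop("eps must be a single positive number", call. = FALSE)
  }
  invisible(eps)
}

#' Region primitives for contour initialization
#'
#' Geometric descriptions of the initial interior region. Coordinates are
#' pixel centers in `(row, col)`, 0-based, matching the raster convention of
#' the whole package. The circle is inclusive (`distance <= radius`); the
#' rectangle is half-open (`row0 <= row < row1`, `col0 <= col < col1`).
#'
#' @param row,col Center of the circle (0-based pixel coordinates).
#' @param radius Circle radius in pixels.
#' @return A region object understood by [init_levelset()].
#' @examples
#' region_circle(4, 4, 2)
#' region_rect(0, 0, 4, 8)
#' @name regions
NULL

#' @rdname regions
#' @export
region_circle <- function(row, col, radius) {
  stopifnot(is.numeric(row), is.numeric(col), is.numeric(radius), radius > 0)
  structure(list(type = "circle", row = row, col = col, radius = radius),
            class = "init_region")
}

#' @rdname regions
#' @param row0,col0,row1,col1 Corners of the half-open rectangle.
#' @export
region_rect <- function(row0, col0, row1, col1) {
  stopifnot(row1 > row0, col1 > col0)
  structure(list(type = "rect", row0 = row0, col0 = col0,
                 row1 = row1, col1 = col1),
            class = "init_region")
}

#' @rdname regions
#' @param mask Logical matrix marking the interior region.
#' @export
region_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  structure(list(type = "mask", mask = mask != 0), class = "init_region")
}

region_to_mask <- function(region, shape) {
  nr <- shape[1]; nc <- shape[2]
  if (inherits(region, "init_region")) {
    switch(region$type,
      circle = {
        rows <- matrix(0:(nr - 1), nr, nc)
        cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
        (rows - region$row)^2 + (cols - region$col)^2 <= region$radius^2
      },
      rect = {
        rows <- matrix(0:(nr - 1), nr, nc)
        cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
        rows >= region$row0 & rows < region$row1 &
          cols >= region$col0 & cols < region$col1
      },
      mask = {
        if (!all(dim(region$mask) == shape)) {
          stop("mask region shape does not match the image", call. = FALSE)
        }
        region$mask
      },
      stop("unknown region type", call. = FALSE)
    )
  } else if (is.matrix(region) && (is.logical(region) || is.numeric(region))) {
    if (!all(dim(region) == shape)) {
      stop("mask region shape does not match the image", call. = FALSE)
    }
    region != 0
  } else {
    stop("region must be an init_region or a matrix mask", call. = FALSE)
  }
}

#' Initialize a level-set field as a binary step
#'
#' Builds the starting field \eqn{\phi_0 = +c_0} inside the given region and
#' \eqn{-c_0} outside, honoring the convention that \eqn{\phi > 0} marks the
#' interior of the contour. `invert = TRUE` flips the sign assignment.
#'
#' @param shape Integer vector `(rows, cols)`.
#' @param region An [region_circle()]/[region_rect()]/[region_mask()] object
#'   or a logical matrix.
#' @param c0 Positive step magnitude.
#' @param invert If `TRUE`, assign `-c0` inside (the opposite convention).
#' @return Numeric matrix with values in `{-c0, +c0}`.
#' @examples
#' phi <- init_levelset(c(8, 8), region_circle(4, 4, 2), c0 = 2)
#' table(phi)
#' @export
init_levelset <- function(shape, region, c0 = 2, invert = FALSE) {
  if (c0 <= 0) stop("c0 must be positive", call. = FALSE)
  m <- region_to_mask(region, shape)
  if (!any(m) || all(m)) {
    stop("initial region must be a nonempty proper subset of the image",
         call. = FALSE)
  }
  s <- if (invert) -c0 else c0
  ifelse(m, s, -s)
}

# Central differences with replicate (Neumann) boundary handling. At the
# borders this reduces to a half-weight one-sided difference, consistent with
# padding by edge replication.
grad_row <- function(m) {
  nr <- nrow(m)
  if (nr == 1L) return(m * 0)
  (m[c(2:nr, nr), , drop = FALSE] - m[c(1, 1:(nr - 1)), , drop = FALSE]) / 2
}

grad_col <- function(m) {
  nc <- ncol(m)
  if (nc == 1L) return(m * 0)
  (m[, c(2:nc, nc), drop = FALSE] - m[, c(1, 1:(nc - 1)), drop = FALSE]) / 2
}

#' Mean curvature of the level lines
#'
#' Central-difference approximation of \eqn{\mathrm{div}(\nabla\phi /
#' |\nabla\phi|)} with replicate boundary handling. The gradient magnitude is
#' regularized as \eqn{\sqrt{\phi_x^2 + \phi_y^2 + \eta^2}} with
#' \eqn{\eta = 10^{-8}}, so the result is finite even where \eqn{\nabla\phi = 0}.
#'
#' @param phi Level-set field (numeric matrix, finite).
#' @return Curvature field of the same shape.
#' @examples
#' phi <- outer(1:32, 1:32, function(i, j) i + j)  # straight level lines
#' max(abs(curvature(phi)))
#' @export
curvature <- function(phi) {
  stopifnot(is.matrix(phi))
  if (!all(is.finite(phi))) stop("phi must be finite", call. = FALSE)
  eta <- 1e-8
  px <- grad_col(phi)
  py <- grad_row(phi)
  nrm <- sqrt(px^2 + py^2 + eta^2)
  grad_col(px / nrm) + grad_row(py / nrm)
}

#' Binary mask of the contour interior
#'
#' The interior is the strict superlevel set `phi > 0`; pixels with exactly
#' zero are assigned to the outside so ties break deterministically.
#'
#' @param phi Level-set field.
#' @return Logical matrix of the same shape.
#' @export
mask_from_levelset <- function(phi) {
  phi > 0
}
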