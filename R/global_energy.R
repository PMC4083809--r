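#' Global region means
#'
#' Mean intensity of the contour interior (`m`) and exterior (`n`), with the
#' regions weighted by the regularized Heaviside of the level-set field:
#' \deqn{m = \frac{\sum I\,H_\epsilon(\phi)}{\sum H_\epsilon(\phi)}, \qquad
#'       n = \frac{\sum I\,(1-H_\epsilon(\phi))}{\sum (1-H_\epsilon(\phi))}.}
#'
#' @param I Image matrix (intensities in `[0, 1]`).
#' @param phi Level-set field, same shape as `I`.
#' @param eps Heaviside regularization width.
#' @return A `global_stats` object: list with elements `m` and `n`.
#' @examples
#' I <- matrix(runif(64), 8, 8)
#' phi <- init_levelset(c(8, 8), region_circle(4, 4, 2))
#' global_means(I, phi, eps = 1)
#' @export
global_means <- function(I, phi, eps) {
  check_same_shape(I, phi)
  h <- heaviside_eps(phi, eps)
  sh <- sum(h)
  sh1 <- sum(1 - h)
  if (sh < 1e-12 || sh1 < 1e-12) {
    stop("degenerate region: one side of the contour has vanishing area",
         call. = FALSE)
  }
  structure(list(m = sum(I * h) / sh, n = sum(I * (1 - h)) / sh1),
            class = "global_stats")
}

#' Global fitting energy
#'
#' Discrete Chan-Vese style fitting residual
#' \eqn{\sum H_\epsilon(\phi)(I-m)^2 + (1-H_\epsilon(\phi))(I-n)^2}
#' (unit pixel area). Nonnegative; zero for a constant image.
#'
#' @inheritParams global_means
#' @param stats A `global_stats` object from [global_means()].
#' @return Scalar energy.
#' @export
global_energy <- function(I, phi, stats, eps) {
  check_same_shape(I, phi)
  h <- heaviside_eps(phi, eps)
  sum(h * (I - stats$m)^2 + (1 - h) * (I - stats$n)^2)
}

#' Global fitting force
#'
#' Per-pixel velocity contribution of the global term,
#' \eqn{-(I-m)^2 + (I-n)^2}, returned without the \eqn{\delta_\epsilon} and
#' \eqn{\alpha} factors (the evolver applies those when composing terms).
#' Algebraically identical to the factored form \eqn{(m-n)(2I-m-n)}.
#'
#' @inheritParams global_energy
#' @return Force field of the same shape as `I`.
#' @export
global_force <- function(I, stats) {
  -(I - stats$m)^2 + (I - stats$n)^2
}

check_same_shape <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b))) {
    stop("image and level-set field must be matrices of the same shape",
         call. = FALSE)
  }
  invisible(NULL)
}
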