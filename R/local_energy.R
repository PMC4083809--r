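#' Ball localization kernel
#'
#' Binary stencil selecting pixels strictly within Euclidean distance `r` of
#' the center, on a square window of side `2 ceil(r) + 1`. This is the mask
#' that restricts region statistics to a local neighborhood of each pixel.
#'
#' @param r Ball radius in pixels (`r >= 1`). The inequality is strict, so
#'   `r = 1` selects only the center pixel.
#' @return A `ball_kernel` object: list with `r` and the 0/1 `window` matrix.
#' @examples
#' sum(ball_kernel(1)$window)    # 1
#' sum(ball_kernel(1.5)$window)  # full 3x3 neighborhood (sqrt(2) < 1.5)
#' @export
ball_kernel <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 1) {
    stop("ball radius r must be a single number >= 1", call. = FALSE)
  }
  k <- ceiling(r)
  off <- -k:k
  d2 <- outer(off^2, off^2, `+`)
  structure(list(r = r, window = (d2 < r^2) * 1), class = "ball_kernel")
}

#' Ball correlation of a field
#'
#' Correlates a field with the ball stencil, summing in-domain pixels only:
#' `(B %*% f)(x) = sum over y in the image with ||x - y|| < r of f(y)`.
#' This is the exact discretization of the local region integrals over the
#' image domain; no values are invented beyond the image border, so the
#' effective ball area shrinks near edges.
#'
#' @param x Numeric matrix.
#' @param kernel A [ball_kernel()].
#' @return Matrix of the same shape.
#' @export
ball_correlate <- function(x, kernel) {
  stopifnot(is.matrix(x), inherits(kernel, "ball_kernel"))
  ball_correlate_cpp(x, kernel$window)
}

ball_correlate_many <- function(xs, kernel) {
  ball_correlate_many_cpp(xs, kernel$window)
}

#' Local interior/exterior statistics
#'
#' For every pixel `x`, the mean intensity and area of the contour interior
#' and exterior restricted to the ball centered at `x`:
#' \deqn{A_u = B \ast H_\epsilon(\phi), \quad A_v = B \ast (1 - H_\epsilon(\phi)),}
#' \deqn{u_x = (B \ast (H_\epsilon(\phi) I)) / A_u, \quad
#'       v_x = (B \ast ((1-H_\epsilon(\phi)) I)) / A_v.}
#' `Av` is obtained as (local ball area − `Au`), so ball mass is conserved
#' exactly. A denominator below `1e-10` (ball entirely on one side of a very
#' sharp contour) marks the mean undefined at that pixel: the corresponding
#' entry of `ok` is `FALSE`, `u`/`v` are set to 0 there, and such centers
#' contribute zero to the local force and energies.
#'
#' @inheritParams global_means
#' @param kernel A [ball_kernel()].
#' @param cache Optional [ball_cache()] of `I`-dependent correlations,
#'   reused across iterations by the evolver.
#' @return A `local_stats` object: list of matrices `u`, `v`, `Au`, `Av`,
#'   logical `ok`, plus the local ball-area field `area`.
#' @export
local_stats <- function(I, phi, kernel, eps, cache = NULL) {
  check_same_shape(I, phi)
  if (is.null(cache)) cache <- ball_cache(I, kernel)
  h <- heaviside_eps(phi, eps)
  cs <- ball_correlate_many(list(h, h * I), kernel)
  Au <- cs[[1]]
  Av <- cache$area - Au
  cv_ <- cache$corrI - cs[[2]]
  ok <- Au > 1e-10 & Av > 1e-10
  u <- matrix(0, nrow(I), ncol(I))
  v <- matrix(0, nrow(I), ncol(I))
  u[ok] <- cs[[2]][ok] / Au[ok]
  v[ok] <- cv_[ok] / Av[ok]
  structure(list(u = u, v = v, Au = Au, Av = Av, ok = ok,
                 area = cache$area),
            class = "local_stats")
}

#' Precomputed image-side ball correlations
#'
#' The ball correlations that do not depend on the level-set field: the
#' local in-domain ball area `B * 1`, `B * I` and `B * I^2`. Computing them
#' once per evolution saves three correlations per iteration.
#'
#' @inheritParams local_stats
#' @return A `ball_cache` list with elements `area`, `corrI`, `corrI2`.
#' @export
ball_cache <- function(I, kernel) {
  cs <- ball_correlate_many(list(matrix(1, nrow(I), ncol(I)), I, I^2), kernel)
  structure(list(area = cs[[1]], corrI = cs[[2]], corrI2 = cs[[3]]),
            class = "ball_cache")
}

#' Local mean-separation energy (as printed)
#'
#' The double sum \eqn{\sum_x \sum_y B(x,y) (u_x - v_x)^2}: the inner sum
#' over `y` contributes the in-domain ball area at `x`, so the value is
#' \eqn{\sum_x \mathrm{area}(x)\,(u_x - v_x)^2} over centers with defined
#' statistics. Note this quantity *rewards* separation of the local means;
#' the evolution equation descends the local fitting residuals instead (see
#' [local_residual_energy()]), and the energy trace records both.
#'
#' @inheritParams local_stats
#' @param stats Optional precomputed [local_stats()].
#' @return Scalar, nonnegative.
#' @export
local_energy <- function(I, phi, kernel, eps, stats = NULL) {
  if (is.null(stats)) stats <- local_stats(I, phi, kernel, eps)
  stopifnot(inherits(stats, "local_stats"))
  sum((stats$area * (stats$u - stats$v)^2)[stats$ok])
}

#' Local fitting residual energy
#'
#' \eqn{\sum_x \sum_y B(x,y)\,[H_\epsilon(\phi(y))(I(y)-u_x)^2 +
#' (1-H_\epsilon(\phi(y)))(I(y)-v_x)^2]}: the ball-restricted two-phase
#' fitting residual aggregated over all centers. This is the quantity the
#' gradient flow drives down; it is recorded in the energy trace alongside
#' the printed mean-separation form.
#'
#' @inheritParams local_energy
#' @return Scalar, nonnegative.
#' @export
local_residual_energy <- function(I, phi, kernel, eps, stats = NULL,
                                  cache = NULL) {
  if (is.null(stats)) stats <- local_stats(I, phi, kernel, eps, cache)
  q <- if (is.null(cache)) ball_correlate(I^2, kernel) else cache$corrI2
  sum((q - stats$u^2 * stats$Au - stats$v^2 * stats$Av)[stats$ok])
}

#' Local fitting force
#'
#' Per-pixel velocity contribution of the local term: pixel `y` accumulates
#' a residual contrast against the ball statistics of every center `x` whose
#' ball covers it. Two forms of the integrand are available:
#' \describe{
#'   \item{`"mean_separation"` (default)}{the gradient-descent direction of
#'     the localized mean-separation energy,
#'     \deqn{F(y) = \sum_x B(x,y)\,(u_x - v_x)\left[\frac{I(y)-u_x}{A_u(x)}
#'       + \frac{I(y)-v_x}{A_v(x)}\right].}
#'     This is the flow obtained by localizing the coupled-curve-evolution
#'     (mean separation) energy, and the force the hybrid evolution uses: it
#'     pushes contour pixels so that local interior/exterior means pull
#'     apart, and it is a true descent direction (the local fitting residual
#'     decreases along it).}
#'   \item{`"as_printed"`}{the raw form
#'     \eqn{(I(y)-u_x)^2/A_u - (I(y)-v_x)^2/A_v}, which differs from the
#'     negative of the mean-separation direction only by a term that
#'     vanishes where \eqn{A_u = A_v}. It is kept for comparison; as a
#'     velocity it does not converge to the object boundary.}
#' }
#' Either form is computed with ball correlations of center fields (e.g.
#' `F = I (B*((u-v)(a+b))) - (B*((u-v)(u a + v b)))` with `a = 1/Au`,
#' `b = 1/Av` for the default). Returned without the \eqn{\delta_\epsilon}
#' and \eqn{\beta} factors. Centers with degenerate statistics contribute
#' zero.
#'
#' @inheritParams local_stats
#' @param stats A [local_stats()] computed from the same `I`, `phi`,
#'   `kernel`, `eps`.
#' @param form `"mean_separation"` or `"as_printed"`.
#' @return Force field of the same shape as `I`.
#' @export
local_force <- function(I, phi, stats, kernel, eps,
                        form = c("mean_separation", "as_printed")) {
  form <- match.arg(form)
  check_same_shape(I, phi)
  a <- matrix(0, nrow(I), ncol(I))
  b <- matrix(0, nrow(I), ncol(I))
  a[stats$ok] <- 1 / stats$Au[stats$ok]
  b[stats$ok] <- 1 / stats$Av[stats$ok]
  if (form == "mean_separation") {
    sep <- stats$u - stats$v
    cs <- ball_correlate_many(
      list(sep * (a + b), sep * (stats$u * a + stats$v * b)),
      kernel
    )
    I * cs[[1]] - cs[[2]]
  } else {
    cs <- ball_correlate_many(
      list(a - b, a * stats$u - b * stats$v, a * stats$u^2 - b * stats$v^2),
      kernel
    )
    I^2 * cs[[1]] - 2 * I * cs[[2]] + cs[[3]]
  }
}
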