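#' Parameters of the hybrid active-contour evolution
#'
#' Bundles and validates every tunable of the hybrid level-set model: the
#' term weights, the time step, the Heaviside regularization width, the
#' localization radius, and the iteration/stopping controls.
#'
#' @param alpha Weight of the global (Chan-Vese) fitting term. Nonnegative;
#'   with `beta`, typically in `[0, 2]` with `alpha ~ beta`.
#' @param beta Weight of the ball-localized term. Nonnegative.
#' @param omega Weight of the arc-length regularizer.
#' @param dt Explicit Euler time step.
#' @param eps Width of the arctan-regularized Heaviside, in level-set units.
#'   The default 1.0 gives the delta function effectively global support,
#'   which helps the flow act on pixels far from the current contour.
#' @param r Ball radius in pixels for the local statistics.
#' @param c0 Magnitude of the binary step initialization.
#' @param max_iters Iteration cap.
#' @param tol Stopping tolerance: the evolution is declared converged when
#'   the fraction of pixels whose label changed over the last `check_every`
#'   iterations falls below `tol`.
#' @param check_every Iterations between convergence checks / energy records.
#' @param stats_every Iterations between recomputations of the region
#'   statistics (1 = every step).
#'
#' @return An object of class `hybrid_params` (a validated named list).
#' @examples
#' hybrid_params()
#' hybrid_params(alpha = 2, beta = 2, r = 5)
#' @export
hybrid_params <- function(alpha = 1, beta = 1, omega = 0.1, dt = 0.45,
                          eps = 1, r = 9, c0 = 2, max_iters = 2000,
                          tol = 1e-4, check_every = 20, stats_every = 1) {
  p <- list(alpha = alpha, beta = beta, omega = omega, dt = dt, eps = eps,
            r = r, c0 = c0, max_iters = max_iters, tol = tol,
            check_every = check_every, stats_every = stats_every)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  if (alpha < 0 || beta < 0 || omega < 0) {
    stop("alpha, beta and omega must be nonnegative", call. = FALSE)
  }
  if (alpha == 0 && beta == 0 && omega == 0) {
    stop("at least one of alpha, beta, omega must be positive", call. = FALSE)
  }
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  if (r < 1) stop("ball radius r must be >= 1", call. = FALSE)
  if (c0 <= 0) stop("c0 must be positive", call. = FALSE)
  if (max_iters < 0) stop("max_iters must be >= 0", call. = FALSE)
  if (tol < 0) stop("tol must be >= 0", call. = FALSE)
  if (check_every < 1) stop("check_every must be >= 1", call. = FALSE)
  if (stats_every < 1) stop("stats_every must be >= 1", call. = FALSE)
  structure(p, class = "hybrid_params")
}

#' @export
print.hybrid_params <- function(x, ...) {
  cat("<hybrid_params>\n")
  cat(sprintf("  weights: alpha=%g beta=%g omega=%g\n", x$alpha, x$beta, x$omega))
  cat(sprintf("  numerics: dt=%g eps=%g r=%g c0=%g\n", x$dt, x$eps, x$r, x$c0))
  cat(sprintf("  stopping: max_iters=%d tol=%g check_every=%d stats_every=%d\n",
              as.integer(x$max_iters), x$tol, as.integer(x$check_every),
              as.integer(x$stats_every)))
  invisible(x)
}
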